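ethanol_perm
     RDKit          3D

  9  8  0  0  0  0  0  0  0  0999 V2000
    1.4671    1.1550    0.0848 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8883    0.1670   -0.0273 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4658   -0.5116   -0.0368 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4311    0.3229    0.5867 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8487    1.1175   -0.5695 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6471   -0.4704   -0.4896 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1964    0.3978    0.9977 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7920   -0.7224   -1.0597 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4246   -1.4559    0.5138 H   0  0  0  0  0  0  0  0  0  0  0  0
  2  3  1  0
  3  4  1  0
  2  5  1  0
  2  6  1  0
  2  7  1  0
  3  8  1  0
  3  9  1  0
  4  1  1  0
M  END
$$$$
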