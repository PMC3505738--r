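benzene
     RDKit          3D

 12 12  0  0  0  0  0  0  0  0999 V2000
    0.8077   -1.1370    0.0184 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3887    0.1309   -0.0046 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5809    1.2679   -0.0231 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8077    1.1370   -0.0184 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3887   -0.1309    0.0046 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5809   -1.2679    0.0231 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4370   -2.0229    0.0328 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4706    0.2328   -0.0082 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0336    2.2557   -0.0410 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4370    2.0229   -0.0328 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4706   -0.2328    0.0082 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0336   -2.2557    0.0410 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0
  2  3  1  0
  3  4  2  0
  4  5  1  0
  5  6  2  0
  6  1  1  0
  1  7  1  0
  2  8  1  0
  3  9  1  0
  4 10  1  0
  5 11  1  0
  6 12  1  0
M  END
$$$$
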