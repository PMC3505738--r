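butane
     RDKit          3D

 14 13  0  0  0  0  0  0  0  0999 V2000
   -1.5741    0.4734    0.0236 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5553   -0.3111   -0.7888 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6465   -0.7800    0.0318 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5044    0.3614    0.5557 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1601    1.4220    0.3776 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9127   -0.1023    0.8907 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4491    0.7033   -0.5929 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2152    0.2992   -1.6336 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0516   -1.1918   -1.2136 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3069   -1.3960    0.8725 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2701   -1.4230   -0.6008 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3934   -0.0361    1.0558 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9601    0.9710    1.2829 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.8369    1.0100   -0.2609 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  1  5  1  0
  1  6  1  0
  1  7  1  0
  2  8  1  0
  2  9  1  0
  3 10  1  0
  3 11  1  0
  4 12  1  0
  4 13  1  0
  4 14  1  0
M  END
$$$$
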