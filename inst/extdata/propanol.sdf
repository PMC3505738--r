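n-propanol
     RDKit          3D

 12 11  0  0  0  0  0  0  0  0999 V2000
   -1.3061   -0.0154    0.5024 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1415    0.6492   -0.2174 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9134   -0.3560   -0.6626 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4916   -1.0131    0.4565 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0537    0.7337    0.7819 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9747   -0.5175    1.4168 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7920   -0.7563   -0.1404 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5185    1.1908   -1.0918 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3111    1.3832    0.4593 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4766   -1.1166   -1.3173 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.7128    0.1476   -1.2154 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.8809   -0.3296    1.0282 H   0  0  0  0  0  0  0  0  0  0  0  0
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
M  END
$$$$
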