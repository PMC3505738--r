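acetanilide
     RDKit          3D

 19 19  0  0  0  0  0  0  0  0999 V2000
    3.4037   -0.6248    0.1047 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9455   -0.8554    0.4159 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6004   -1.7791    1.1438 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.1295    0.0881   -0.1816 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2758    0.1815   -0.1049 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0808   -0.7099    0.6061 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4700   -0.5464    0.6304 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0657    0.5088   -0.0560 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2725    1.4032   -0.7687 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8848    1.2399   -0.7929 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.9541   -1.5620    0.2280 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8060    0.1256    0.7903 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.5350   -0.2887   -0.9279 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5879    0.8018   -0.7331 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6603   -1.5468    1.1547 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0838   -1.2489    1.1889 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.1452    0.6319   -0.0342 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7329    2.2282   -1.3061 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2902    1.9530   -1.3575 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  2  4  1  0
  4  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  2  0
  8  9  1  0
  9 10  2  0
 10  5  1  0
  1 11  1  0
  1 12  1  0
  1 13  1  0
  4 14  1  0
  6 15  1  0
  7 16  1  0
  8 17  1  0
  9 18  1  0
 10 19  1  0
M  END
$$$$
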