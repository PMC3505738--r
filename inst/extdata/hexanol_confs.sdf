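hexanol
     RDKit          3D

 21 20  0  0  0  0  0  0  0  0999 V2000
   -3.1840    0.2746   -0.3038 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7904   -0.2736   -0.0362 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7550    0.3587   -0.9670 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6461   -0.2423   -0.8186 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2885    0.0416    0.5430 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7116   -0.5016    0.6304 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5600    0.1413   -0.3103 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9092   -0.1868    0.3739 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4982    0.0643   -1.3311 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2155    1.3578   -0.1492 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5332   -0.0776    1.0100 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8001   -1.3611   -0.1726 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7115    1.4408   -0.7933 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0771    0.2193   -2.0066 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2776    0.1745   -1.6126 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6013   -1.3251   -0.9874 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6947   -0.4121    1.3432 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.3027    1.1253    0.7100 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7319   -1.5775    0.4308 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.1228   -0.3353    1.6312 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.5370    1.0949   -0.1216 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  1  8  1  0
  1  9  1  0
  1 10  1  0
  2 11  1  0
  2 12  1  0
  3 13  1  0
  3 14  1  0
  4 15  1  0
  4 16  1  0
  5 17  1  0
  5 18  1  0
  6 19  1  0
  6 20  1  0
  7 21  1  0
M  END
$$$$
hexanol
     RDKit          3D

 21 20  0  0  0  0  0  0  0  0999 V2000
    2.7027    0.6227   -0.6870 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8588    1.0144    0.5162 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3639    0.7438    0.3272 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0327   -0.7450    0.1947 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4697   -1.0314    0.2163 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2200   -0.4470   -0.9740 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5815   -0.8563   -0.9292 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.7431    0.9251   -0.5302 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3412    1.1123   -1.5968 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6934   -0.4592   -0.8483 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.9966    2.0859    0.7047 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.2243    0.4874    1.4052 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0099    1.2893   -0.5550 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1707    1.1556    1.1921 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4605   -1.1463   -0.7310 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4979   -1.2922    1.0238 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6249   -2.1177    0.2336 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.9116   -0.6583    1.1487 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7931   -0.8027   -1.9168 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.1950    0.6465   -0.9745 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9585   -0.5271   -0.0955 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  1  8  1  0
  1  9  1  0
  1 10  1  0
  2 11  1  0
  2 12  1  0
  3 13  1  0
  3 14  1  0
  4 15  1  0
  4 16  1  0
  5 17  1  0
  5 18  1  0
  6 19  1  0
  6 20  1  0
  7 21  1  0
M  END
$$$$
hexanol
     RDKit          3D

 21 20  0  0  0  0  0  0  0  0999 V2000
   -2.9445   -1.1992   -0.4351 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7069   -0.3256   -0.5736 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8777   -0.3265    0.7112 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3199    0.6264    0.6632 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.3821    0.2164   -0.3555 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6017    1.1277   -0.2881 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5564    0.7283   -1.2624 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5918   -0.8384    0.3706 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6699   -2.2363   -0.2176 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.5220   -1.1882   -1.3648 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1097   -0.6964   -1.4133 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0151    0.6975   -0.8180 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5182   -0.0276    1.5504 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5299   -1.3440    0.9274 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0281    1.6438    0.4470 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7742    0.6540    1.6616 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9767    0.2445   -1.3734 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6929   -0.8212   -0.1822 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0756    1.0882    0.6980 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3240    2.1660   -0.4942 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8103   -0.1893   -1.0648 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  1  8  1  0
  1  9  1  0
  1 10  1  0
  2 11  1  0
  2 12  1  0
  3 13  1  0
  3 14  1  0
  4 15  1  0
  4 16  1  0
  5 17  1  0
  5 18  1  0
  6 19  1  0
  6 20  1  0
  7 21  1  0
M  END
$$$$
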