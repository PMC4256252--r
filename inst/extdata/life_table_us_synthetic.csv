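"age","sex","q"
50,"male",0.005025
51,"male",0.005473
52,"male",0.005961
53,"male",0.006492
54,"male",0.00707
55,"male",0.0077
56,"male",0.008386
57,"male",0.009132
58,"male",0.009945
59,"male",0.010829
60,"male",0.011791
61,"male",0.012839
62,"male",0.013979
63,"male",0.015219
64,"male",0.016569
65,"male",0.018037
66,"male",0.019634
67,"male",0.021371
68,"male",0.023259
69,"male",0.025313
70,"male",0.027544
71,"male",0.02997
72,"male",0.032606
73,"male",0.035469
74,"male",0.038579
75,"male",0.041955
76,"male",0.04562
77,"male",0.049596
78,"male",0.053909
79,"male",0.058586
80,"male",0.063654
81,"male",0.069145
82,"male",0.07509
83,"male",0.081523
84,"male",0.08848
85,"male",0.096
86,"male",0.104122
87,"male",0.112886
88,"male",0.122337
89,"male",0.132518
90,"male",0.143476
91,"male",0.155256
92,"male",0.167904
93,"male",0.181469
94,"male",0.195994
95,"male",0.211526
96,"male",0.228104
97,"male",0.245769
98,"male",0.264554
99,"male",0.284486
100,"male",0.305586
101,"male",0.327865
102,"male",0.351324
103,"male",0.375949
104,"male",0.401714
105,"male",0.428573
106,"male",0.456464
107,"male",0.485301
108,"male",0.514979
109,"male",0.545366
110,"male",1
50,"female",0.002901
51,"female",0.003181
52,"female",0.003489
53,"female",0.003826
54,"female",0.004195
55,"female",0.0046
56,"female",0.005044
57,"female",0.005531
58,"female",0.006064
59,"female",0.006649
60,"female",0.00729
61,"female",0.007993
62,"female",0.008763
63,"female",0.009607
64,"female",0.010531
65,"female",0.011544
66,"female",0.012654
67,"female",0.01387
68,"female",0.015202
69,"female",0.016661
70,"female",0.018258
71,"female",0.020007
72,"female",0.021922
73,"female",0.024017
74,"female",0.026311
75,"female",0.02882
76,"female",0.031564
77,"female",0.034565
78,"female",0.037845
79,"female",0.04143
80,"female",0.045347
81,"female",0.049624
82,"female",0.054293
83,"female",0.059388
84,"female",0.064944
85,"female",0.071
86,"female",0.077597
87,"female",0.084778
88,"female",0.09259
89,"female",0.101081
90,"female",0.110303
91,"female",0.120308
92,"female",0.131152
93,"female",0.142891
94,"female",0.155584
95,"female",0.16929
96,"female",0.184066
97,"female",0.199969
98,"female",0.217056
99,"female",0.235376
100,"female",0.254977
101,"female",0.275897
102,"female",0.298166
103,"female",0.321804
104,"female",0.346815
105,"female",0.373186
106,"female",0.400887
107,"female",0.429862
108,"female",0.460032
109,"female",0.49129
110,"female",1
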