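# symbol=Cl Z=17 atomic_mass=35.4500 k_edge_keV=2.822
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,9744.89,0.010544,3.14183,9748.042374
2,1107.98,0.0321741,2.81759,1110.8297641
2.822,376.276,0.0520614,2.47594,378.8040014
2.822,3198.34,0.0520614,2.47594,3200.8680014
3,2639.98,0.0562863,2.39939,2642.4356763
4,1070.79,0.0783535,1.98269,1072.8510435
5,531.769,0.0968168,1.61929,533.4851068
6,300.16,0.111638,1.32353,301.595168
7,185.08,0.123333,1.09025,186.293583
8,121.746,0.132515,0.907959,122.786474
9,84.1404,0.139735,0.765087,85.045222
10,60.4611,0.145433,0.652091,61.258624
11,45.7045,0.149953,0.561673,46.416126
12,35.4016,0.153554,0.488423,36.043577
13,27.9879,0.156434,0.428364,28.572698
14,22.5157,0.158745,0.378563,23.053008
15,18.3875,0.160599,0.33684,18.884939
16,15.0658,0.162087,0.301554,15.529441
17,12.4942,0.163278,0.271458,12.928936
18,10.473,0.164224,0.245589,10.882813
19,8.86296,0.164969,0.223197,9.251126
20,7.56495,0.165547,0.203691,7.934188
21,6.53716,0.165986,0.186598,6.889744
22,5.68751,0.166307,0.17154,6.025357
23,4.97902,0.16653,0.158209,5.303759
24,4.38354,0.166668,0.146352,4.69656
25,3.8794,0.166734,0.135762,4.181896
26,3.44973,0.166738,0.126267,3.742735
27,3.08128,0.16669,0.117721,3.365691
28,2.7635,0.166596,0.110003,3.040099
29,2.48799,0.166462,0.103011,2.757463
30,2.24793,0.166295,0.0966566,2.5108816
31,2.03162,0.166097,0.090866,2.288583
32,1.84203,0.165874,0.0855747,2.0934787
33,1.67518,0.165627,0.0807274,1.9215344
34,1.52777,0.165362,0.0762763,1.7694083
35,1.39705,0.165078,0.0721795,1.6343075
36,1.28074,0.16478,0.0684009,1.5139209
37,1.17692,0.164468,0.0649085,1.4062965
38,1.08395,0.164145,0.0616743,1.3097693
39,1.00046,0.163812,0.0586738,1.2229458
40,0.925278,0.16347,0.0558851,1.1446331
41,0.856837,0.16312,0.0532889,1.0732459
42,0.794929,0.162764,0.0508679,1.0085609
43,0.738796,0.162402,0.0486069,0.9498049
44,0.687784,0.162035,0.0464922,0.8963112
45,0.641325,0.161663,0.0445115,0.8474995
46,0.598924,0.161288,0.0426537,0.8028657
47,0.56015,0.16091,0.0409091,0.7619691
48,0.524625,0.160529,0.0392686,0.7244226
49,0.492017,0.160146,0.0377241,0.6898871
50,0.462034,0.159762,0.0362684,0.6580644
51,0.434057,0.159376,0.0348948,0.6283278
52,0.408269,0.158989,0.0335973,0.6008553
53,0.384461,0.158601,0.0323704,0.5754324
54,0.362448,0.158213,0.0312091,0.5518701
55,0.342066,0.157824,0.0301088,0.5299988
56,0.323167,0.157436,0.0290654,0.5096684
57,0.305619,0.157048,0.028075,0.490742
58,0.289304,0.15666,0.0271341,0.4730981
59,0.274118,0.156273,0.0262395,0.4566305
60,0.259964,0.155886,0.0253881,0.4412381
61,0.246909,0.1555,0.0245774,0.4269864
62,0.234705,0.155115,0.0238046,0.4136246
63,0.223286,0.154731,0.0230676,0.4010846
64,0.212589,0.154349,0.0223641,0.3893021
65,0.202559,0.153967,0.0216922,0.3782182
66,0.193144,0.153587,0.02105,0.367781
67,0.184299,0.153208,0.0204358,0.3579428
68,0.175981,0.152831,0.0198479,0.3486599
69,0.168152,0.152455,0.0192849,0.3398919
70,0.160777,0.152081,0.0187455,0.3316035
71,0.153822,0.151708,0.0182283,0.3237583
72,0.14726,0.151337,0.0177321,0.3163291
73,0.141062,0.150968,0.0172559,0.3092859
74,0.135205,0.1506,0.0167985,0.3026035
75,0.129664,0.150234,0.016359,0.296257
76,0.124419,0.14987,0.0159364,0.2902254
77,0.119451,0.149508,0.01553,0.284489
78,0.114742,0.149147,0.0151388,0.2790278
79,0.110275,0.148789,0.0147622,0.2738262
80,0.106034,0.148432,0.0143995,0.2688655
81,0.102049,0.148077,0.0140499,0.2641759
82,0.0982597,0.147724,0.0137128,0.2596965
83,0.0946545,0.147373,0.0133877,0.2554152
84,0.0912224,0.147023,0.013074,0.2513194
85,0.0879532,0.146676,0.0127711,0.2474003
86,0.0848374,0.14633,0.0124787,0.2436461
87,0.081866,0.145987,0.0121961,0.2400491
88,0.0790309,0.145645,0.011923,0.2365989
89,0.0763244,0.145305,0.0116589,0.2332883
90,0.0737393,0.144967,0.0114035,0.2301098
91,0.0712689,0.144631,0.0111564,0.2270563
92,0.0689069,0.144297,0.0109172,0.2241211
93,0.0666475,0.143965,0.0106856,0.2212981
94,0.0644851,0.143634,0.0104613,0.2185804
95,0.0624147,0.143306,0.0102439,0.2159646
96,0.0604314,0.142979,0.0100332,0.2134436
97,0.0585307,0.142654,0.00982897,0.21101367
98,0.0567083,0.142331,0.00963088,0.20867018
99,0.0549604,0.14201,0.0094387,0.2064091
100,0.0532831,0.141691,0.0092522,0.2042263
101,0.0516674,0.141374,0.00907117,0.20211257
102,0.0501159,0.141058,0.00889538,0.20006928
103,0.0486254,0.140744,0.00872465,0.19809405
104,0.047193,0.140432,0.00855877,0.19618377
105,0.045816,0.140122,0.00839758,0.19433558
106,0.0444915,0.139814,0.00824088,0.19254638
107,0.0432173,0.139507,0.00808852,0.19081282
108,0.041991,0.139202,0.00794034,0.18913334
109,0.0408102,0.138899,0.00779618,0.18750538
110,0.039673,0.138598,0.00765591,0.18592691
111,0.0385773,0.138298,0.00751938,0.18439468
112,0.0375214,0.138,0.00738647,0.18290787
113,0.0365033,0.137704,0.00725704,0.18146434
114,0.0355215,0.13741,0.00713098,0.18006248
115,0.0345743,0.137117,0.00700817,0.17869947
116,0.0336602,0.136826,0.0068885,0.1773747
117,0.0327778,0.136537,0.00677186,0.17608666
118,0.0319258,0.136249,0.00665816,0.17483296
119,0.0311029,0.135963,0.00654729,0.17361319
120,0.0303078,0.135678,0.00643916,0.17242496
121,0.0295393,0.135395,0.00633369,0.17126799
122,0.0287965,0.135114,0.00623078,0.17014128
123,0.0280781,0.134834,0.00613036,0.16904246
124,0.0273833,0.134556,0.00603234,0.16797164
125,0.026711,0.13428,0.00593665,0.16692765
126,0.0260604,0.134005,0.00584321,0.16590861
127,0.0254306,0.133731,0.00575196,0.16491356
128,0.0248208,0.133459,0.00566283,0.16394263
129,0.0242302,0.133189,0.00557575,0.16299495
130,0.023658,0.13292,0.00549066,0.16206866
131,0.0231036,0.132653,0.0054075,0.1611641
132,0.0225663,0.132387,0.00532621,0.16027951
133,0.0220453,0.132123,0.00524674,0.15941504
134,0.0215402,0.13186,0.00516904,0.15856924
135,0.0210502,0.131598,0.00509304,0.15774124
136,0.0205749,0.131338,0.00501871,0.15693161
137,0.0201137,0.13108,0.00494599,0.15613969
138,0.0196661,0.130823,0.00487483,0.15536393
139,0.0192315,0.130567,0.0048052,0.1546037
140,0.0188096,0.130312,0.00473705,0.15385865
141,0.0183998,0.13006,0.00467034,0.15313014
142,0.0180018,0.129808,0.00460502,0.15241482
143,0.0176151,0.129558,0.00454106,0.15171416
144,0.0172393,0.129309,0.00447843,0.15102673
145,0.016874,0.129061,0.00441708,0.15035208
146,0.0165189,0.128815,0.00435698,0.14969088
147,0.0161736,0.12857,0.0042981,0.1490417
148,0.0158378,0.128327,0.0042404,0.1484052
149,0.0155112,0.128085,0.00418385,0.14778005
150,0.0151934,0.127844,0.00412843,0.14716583
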