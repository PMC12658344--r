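# symbol=Ar Z=18 atomic_mass=39.9480 k_edge_keV=3.206
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,11000.8,0.00885616,3.13287,11003.94172616
2,1250.77,0.0273731,2.82656,1253.6239331
3,350.615,0.0485925,2.42611,353.0897025
3.206,284.682,0.0528905,2.3407,287.0755905
3.206,2419.8,0.0528905,2.3407,2422.1935905
4,1208.79,0.0685756,2.02071,1210.8792856
5,600.304,0.0857334,1.66164,602.0513734
6,338.846,0.0998137,1.36548,340.3112937
7,208.934,0.11113,1.12938,210.17451
8,137.437,0.120153,0.943384,138.500537
9,94.9846,0.12734,0.796736,95.908676
10,68.2535,0.133077,0.680247,69.066824
11,51.67,0.137675,0.586735,52.39441
12,40.0754,0.141373,0.510796,40.727569
13,31.7217,0.144358,0.448415,32.314473
14,25.5483,0.146776,0.396611,26.091687
15,20.886,0.148736,0.353156,21.387892
16,17.1182,0.150326,0.316366,17.584892
17,14.2004,0.151613,0.284958,14.636971
18,11.9065,0.152652,0.257939,12.317091
19,10.0787,0.153485,0.234533,10.466718
20,8.60475,0.154147,0.21413,8.973027
21,7.43972,0.154665,0.19624,7.790625
22,6.47612,0.155062,0.18047,6.811652
23,5.67219,0.155355,0.166501,5.994046
24,4.99618,0.155562,0.154071,5.305813
25,4.42359,0.155693,0.142964,4.722247
26,3.93537,0.15576,0.133,4.22413
27,3.51652,0.155771,0.124029,3.79632
28,3.15513,0.155735,0.115924,3.426789
29,2.84168,0.155657,0.108578,3.105915
30,2.56847,0.155543,0.101901,2.825914
31,2.32146,0.155397,0.0958137,2.5726707
32,2.10495,0.155224,0.0902497,2.3504237
33,1.9144,0.155026,0.0851512,2.1545772
34,1.74603,0.154807,0.0804681,1.9813051
35,1.59673,0.15457,0.0761569,1.8274569
36,1.46387,0.154317,0.0721794,1.6903664
37,1.34527,0.154049,0.0685025,1.5678215
38,1.23907,0.153768,0.0650968,1.4579348
39,1.14369,0.153477,0.0619364,1.3591034
40,1.05779,0.153175,0.0589986,1.2699636
41,0.979465,0.152866,0.0562631,1.1885941
42,0.908619,0.152548,0.0537119,1.1148789
43,0.844388,0.152224,0.0513289,1.0479409
44,0.786021,0.151895,0.0490997,0.9870157
45,0.732868,0.15156,0.0470114,0.9314394
46,0.684361,0.151222,0.0450526,0.8806356
47,0.640007,0.150879,0.0432128,0.8340988
48,0.599372,0.150533,0.0414826,0.7913876
49,0.562078,0.150185,0.0398535,0.7521165
50,0.527788,0.149835,0.0383178,0.7159408
51,0.495678,0.149482,0.0368687,0.6820287
52,0.46609,0.149128,0.0354996,0.6507176
53,0.438782,0.148773,0.034205,0.62176
54,0.413541,0.148417,0.0329794,0.5949374
55,0.390175,0.14806,0.0318182,0.5700532
56,0.368516,0.147703,0.0307169,0.5469359
57,0.348411,0.147346,0.0296714,0.5254284
58,0.329724,0.146989,0.0286781,0.5053911
59,0.312334,0.146631,0.0277337,0.4866987
60,0.296131,0.146275,0.0268348,0.4692408
61,0.281195,0.145918,0.0259787,0.4530917
62,0.267237,0.145563,0.0251628,0.4379628
63,0.254179,0.145207,0.0243845,0.4237705
64,0.24195,0.144853,0.0236416,0.4104446
65,0.230485,0.1445,0.0229319,0.3979169
66,0.219727,0.144148,0.0222536,0.3861286
67,0.209621,0.143797,0.0216048,0.3750228
68,0.20012,0.143447,0.0209839,0.3645509
69,0.191178,0.143098,0.0203892,0.3546652
70,0.182757,0.14275,0.0198194,0.3453264
71,0.174818,0.142404,0.019273,0.336495
72,0.167327,0.142059,0.0187488,0.3281348
73,0.160255,0.141716,0.0182456,0.3202166
74,0.153572,0.141374,0.0177623,0.3127083
75,0.147251,0.141034,0.017298,0.305583
76,0.141269,0.140695,0.0168515,0.2988155
77,0.135604,0.140357,0.016422,0.292383
78,0.130235,0.140022,0.0160087,0.2862657
79,0.125143,0.139688,0.0156107,0.2804417
80,0.12031,0.139355,0.0152273,0.2748923
81,0.115766,0.139024,0.0148579,0.2696479
82,0.111446,0.138695,0.0145017,0.2646427
83,0.107336,0.138368,0.0141581,0.2598621
84,0.103425,0.138042,0.0138265,0.2552935
85,0.0997004,0.137718,0.0135064,0.2509248
86,0.0961509,0.137396,0.0131973,0.2467442
87,0.0927667,0.137075,0.0128986,0.2427403
88,0.0895382,0.136756,0.0126099,0.2389041
89,0.0864567,0.136439,0.0123308,0.2352265
90,0.0835139,0.136123,0.0120608,0.2316977
91,0.0807022,0.135809,0.0117996,0.2283108
92,0.0780143,0.135497,0.0115467,0.225058
93,0.0754435,0.135187,0.0113019,0.2219324
94,0.0729837,0.134878,0.0110647,0.2189264
95,0.0706288,0.134571,0.0108349,0.2160347
96,0.0683733,0.134266,0.0106122,0.2132515
97,0.0662122,0.133962,0.0103963,0.2105705
98,0.0641405,0.13366,0.0101868,0.2079873
99,0.0621536,0.13336,0.00998366,0.20549726
100,0.0602474,0.133062,0.00978648,0.20309588
101,0.0583991,0.132765,0.00959508,0.20075918
102,0.056625,0.13247,0.00940922,0.19850422
103,0.0549212,0.132176,0.0092287,0.1963259
104,0.0532845,0.131884,0.00905331,0.19422181
105,0.0517115,0.131594,0.00888287,0.19218837
106,0.0501992,0.131306,0.00871718,0.19022238
107,0.0487447,0.131019,0.00855608,0.18831978
108,0.0473452,0.130734,0.00839939,0.18647859
109,0.0459984,0.13045,0.00824696,0.18469536
110,0.0447016,0.130168,0.00809863,0.18296823
111,0.0434526,0.129888,0.00795426,0.18129486
112,0.0422492,0.129609,0.00781371,0.17967191
113,0.0410895,0.129332,0.00767684,0.17809834
114,0.0399713,0.129056,0.00754354,0.17657084
115,0.038893,0.128782,0.00741367,0.17508867
116,0.0378527,0.128509,0.00728711,0.17364881
117,0.0368488,0.128238,0.00716377,0.17225057
118,0.0358798,0.127969,0.00704352,0.17089232
119,0.0349441,0.127701,0.00692628,0.16957138
120,0.0340403,0.127434,0.00681193,0.16828623
121,0.0331671,0.127169,0.00670038,0.16703648
122,0.0323232,0.126906,0.00659155,0.16582075
123,0.0315074,0.126644,0.00648534,0.16463674
124,0.0307186,0.126383,0.00638168,0.16348328
125,0.0299556,0.126124,0.00628047,0.16236007
126,0.0292174,0.125867,0.00618165,0.16126605
127,0.028503,0.12561,0.00608515,0.16019815
128,0.0278115,0.125356,0.00599088,0.15915838
129,0.027142,0.125102,0.00589878,0.15814278
130,0.0264936,0.12485,0.00580878,0.15715238
131,0.0258654,0.1246,0.00572083,0.15618623
132,0.0252568,0.124351,0.00563486,0.15524266
133,0.0246669,0.124103,0.0055508,0.1543207
134,0.024095,0.123856,0.00546862,0.15341962
135,0.0235405,0.123611,0.00538824,0.15253974
136,0.0230027,0.123368,0.00530961,0.15168031
137,0.0224811,0.123125,0.0052327,0.1508388
138,0.0219749,0.122884,0.00515744,0.15001634
139,0.0214836,0.122644,0.00508379,0.14921139
140,0.0210067,0.122406,0.0050117,0.1484244
141,0.0205437,0.122169,0.00494114,0.14765384
142,0.0200941,0.121933,0.00487205,0.14689915
143,0.0196574,0.121698,0.0048044,0.1461598
144,0.019233,0.121465,0.00473815,0.14543615
145,0.0188207,0.121233,0.00467325,0.14472695
146,0.01842,0.121002,0.00460968,0.14403168
147,0.0180305,0.120773,0.0045474,0.1433509
148,0.0176517,0.120544,0.00448636,0.14268206
149,0.0172834,0.120317,0.00442655,0.14202695
150,0.0169252,0.120091,0.00436793,0.14138413
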