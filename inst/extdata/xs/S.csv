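# symbol=S Z=16 atomic_mass=32.0600 k_edge_keV=2.472
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,8347.64,0.0123493,3.06943,8350.7217793
2,949.111,0.0371227,2.73415,951.8822727
2.472,488.293,0.0499228,2.53725,490.8801728
2.472,4150.49,0.0499228,2.53725,4153.0771728
3,2261.45,0.0638774,2.30814,2263.8220174
4,917.253,0.0875939,1.89101,919.2316039
5,455.522,0.106886,1.53325,457.162136
6,257.123,0.122014,1.24618,258.491194
7,158.543,0.133723,1.02226,159.698983
8,104.29,0.142772,0.848725,105.281497
9,72.0761,0.14979,0.713532,72.939422
10,51.792,0.155265,0.607076,52.554341
11,39.091,0.159561,0.522163,39.772724
12,30.2363,0.162949,0.453538,30.852787
13,23.8735,0.165632,0.397377,24.436509
14,19.1827,0.16776,0.350878,19.701338
15,15.6481,0.16945,0.311971,16.129521
16,12.817,0.170788,0.279102,13.26689
17,10.626,0.171841,0.251095,11.048936
18,8.90446,0.172663,0.227042,9.304165
19,7.53349,0.173294,0.206239,7.913023
20,6.42851,0.173768,0.188129,6.790407
21,5.55192,0.174111,0.172271,5.898302
22,4.82767,0.174344,0.158309,5.160323
23,4.22407,0.174484,0.145955,4.544509
24,3.71702,0.174546,0.134973,4.026539
25,3.28795,0.174541,0.12517,3.587661
26,2.92243,0.174479,0.116383,3.213292
27,2.60914,0.174368,0.108478,2.891986
28,2.33905,0.174215,0.101343,2.614608
29,2.10498,0.174026,0.0948806,2.3738866
30,1.90112,0.173805,0.0890101,2.1639351
31,1.71807,0.173558,0.0836619,1.9752899
32,1.55764,0.173286,0.0787764,1.8097024
33,1.41646,0.172994,0.0743021,1.6637561
34,1.29174,0.172685,0.0701946,1.5346196
35,1.18115,0.17236,0.066415,1.419925
36,1.08275,0.172021,0.0629298,1.3177008
37,0.994919,0.171671,0.0597093,1.2262993
38,0.916279,0.17131,0.0567276,1.1443166
39,0.845661,0.170941,0.0539618,1.0705638
40,0.782072,0.170564,0.0513918,1.0040278
41,0.72429,0.17018,0.0489995,0.9434695
42,0.67202,0.169791,0.0467691,0.8885801
43,0.624621,0.169396,0.0446865,0.8387035
44,0.581543,0.168998,0.0427388,0.7932798
45,0.542306,0.168596,0.0409149,0.7518169
46,0.506494,0.168192,0.0392044,0.7138904
47,0.473742,0.167785,0.0375982,0.6791252
48,0.443732,0.167376,0.0360881,0.6471961
49,0.416184,0.166965,0.0346666,0.6178156
50,0.390852,0.166554,0.0333269,0.5907329
51,0.367303,0.166141,0.032063,0.565507
52,0.34559,0.165728,0.0308691,0.5421871
53,0.325539,0.165315,0.0297404,0.5205944
54,0.306993,0.164902,0.028672,0.500567
55,0.289816,0.164489,0.0276599,0.4819649
56,0.273884,0.164077,0.0267002,0.4646612
57,0.259087,0.163665,0.0257893,0.4485413
58,0.245326,0.163254,0.024924,0.433504
59,0.232513,0.162844,0.0241013,0.4194583
60,0.220568,0.162435,0.0233185,0.4063215
61,0.209541,0.162027,0.0225731,0.3941411
62,0.199231,0.16162,0.0218626,0.3827136
63,0.189582,0.161215,0.0211851,0.3719821
64,0.180541,0.160811,0.0205384,0.3618904
65,0.172062,0.160408,0.0199207,0.3523907
66,0.164101,0.160008,0.0193304,0.3434394
67,0.156621,0.159609,0.0187658,0.3349958
68,0.149584,0.159211,0.0182255,0.3270205
69,0.14296,0.158815,0.0177082,0.3194832
70,0.136718,0.158422,0.0172124,0.3123524
71,0.130831,0.15803,0.0167371,0.3055981
72,0.125275,0.15764,0.0162812,0.2991962
73,0.120027,0.157251,0.0158436,0.2931216
74,0.115066,0.156865,0.0154233,0.2873543
75,0.110372,0.156481,0.0150194,0.2818724
76,0.105928,0.156098,0.0146312,0.2766572
77,0.101718,0.155718,0.0142578,0.2716938
78,0.0977258,0.15534,0.0138985,0.2669643
79,0.0939385,0.154963,0.0135525,0.262454
80,0.0903428,0.154589,0.0132192,0.258151
81,0.0869651,0.154217,0.0128981,0.2540802
82,0.0837528,0.153847,0.0125885,0.2501883
83,0.080696,0.153478,0.0122898,0.2464638
84,0.0777854,0.153112,0.0120017,0.2428991
85,0.0750123,0.152748,0.0117235,0.2394838
86,0.0723689,0.152386,0.0114549,0.2362098
87,0.0698475,0.152026,0.0111953,0.2330688
88,0.0674414,0.151668,0.0109445,0.2300539
89,0.0651439,0.151313,0.010702,0.2271589
90,0.0629491,0.150959,0.0104674,0.2243755
91,0.0608512,0.150607,0.0102404,0.2216986
92,0.0588451,0.150257,0.0100208,0.2191229
93,0.0569257,0.14991,0.00980806,0.21664376
94,0.0550885,0.149564,0.00960205,0.21425455
95,0.053329,0.14922,0.00940245,0.21195145
96,0.0516433,0.148879,0.00920899,0.20973129
97,0.0500276,0.148539,0.00902143,0.20758803
98,0.0484782,0.148201,0.00883953,0.20551873
99,0.0469918,0.147866,0.00866306,0.20352086
100,0.0455652,0.147532,0.00849182,0.20158902
101,0.0442007,0.1472,0.00832559,0.19972629
102,0.0428898,0.14687,0.00816418,0.19792398
103,0.0416301,0.146542,0.00800742,0.19617952
104,0.040419,0.146216,0.00785512,0.19449012
105,0.0392542,0.145892,0.00770711,0.19285331
106,0.0381336,0.14557,0.00756324,0.19126684
107,0.037055,0.14525,0.00742335,0.18972835
108,0.0360166,0.144931,0.0072873,0.1882349
109,0.0350164,0.144615,0.00715496,0.18678636
110,0.0340527,0.1443,0.00702617,0.18537887
111,0.033124,0.143987,0.00690083,0.18401183
112,0.0322285,0.143676,0.00677881,0.18268331
113,0.031365,0.143367,0.00665999,0.18139199
114,0.0305318,0.143059,0.00654426,0.18013506
115,0.0297278,0.142753,0.00643151,0.17891231
116,0.0289516,0.142449,0.00632165,0.17772225
117,0.0282021,0.142147,0.00621458,0.17656368
118,0.0274782,0.141847,0.0061102,0.1754354
119,0.0267787,0.141548,0.00600842,0.17433512
120,0.0261026,0.141251,0.00590916,0.17326276
121,0.025449,0.140956,0.00581234,0.17221734
122,0.024817,0.140662,0.00571787,0.17119687
123,0.0242056,0.14037,0.00562569,0.17020129
124,0.023614,0.14008,0.00553571,0.16922971
125,0.0230415,0.139792,0.00544787,0.16828137
126,0.0224873,0.139505,0.0053621,0.1673544
127,0.0219506,0.139219,0.00527834,0.16644794
128,0.0214308,0.138936,0.00519653,0.16556333
129,0.0209272,0.138654,0.0051166,0.1646978
130,0.0204392,0.138373,0.00503849,0.16385069
131,0.0199661,0.138094,0.00496216,0.16302226
132,0.0195075,0.137817,0.00488755,0.16221205
133,0.0190628,0.137541,0.0048146,0.1614184
134,0.0186314,0.137267,0.00474328,0.16064168
135,0.0182129,0.136994,0.00467353,0.15988043
136,0.0178068,0.136723,0.0046053,0.1591351
137,0.0174126,0.136453,0.00453855,0.15840415
138,0.0170299,0.136185,0.00447324,0.15768814
139,0.0166583,0.135918,0.00440933,0.15698563
140,0.0162974,0.135653,0.00434678,0.15629718
141,0.0159468,0.135389,0.00428555,0.15562135
142,0.0156061,0.135127,0.0042256,0.1549587
143,0.015275,0.134866,0.0041669,0.1543079
144,0.0149532,0.134607,0.00410941,0.15366961
145,0.0146403,0.134349,0.0040531,0.1530424
146,0.0143361,0.134092,0.00399794,0.15242604
147,0.0140401,0.133837,0.0039439,0.151821
148,0.0137523,0.133583,0.00389095,0.15122625
149,0.0134722,0.13333,0.00383905,0.15064125
150,0.0131996,0.133079,0.00378818,0.15006678
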