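# symbol=Pb Z=82 atomic_mass=207.2000 k_edge_keV=88.005
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,63576.5,0.00035373,12.9078,63589.40815373
2,10486.2,0.00122021,12.6359,10498.83712021
3,3654.11,0.00250104,12.206,3666.31850104
4,1729.58,0.00413685,11.6484,1741.23253685
5,968.221,0.0060786,10.9988,979.2258786
6,602.703,0.00828214,10.293,613.00428214
7,403.684,0.0107066,9.56346,413.2581666
8,285.274,0.0133139,8.8371,294.1244139
9,210.023,0.0160686,8.13409,218.1731586
10,159.697,0.0189378,7.46824,167.1841778
11,124.645,0.0218914,6.84785,131.5147414
12,99.4089,0.0249021,6.27683,105.7106321
13,80.7316,0.0279454,5.75589,86.5154354
13.035,80.1692,0.0280523,5.73855,85.9358023
13.035,160.338,0.0280523,5.73855,166.1046023
14,132.502,0.0309996,5.28358,137.8165796
15,110.21,0.0340454,4.85712,115.1011654
15.2,106.38,0.0346521,4.77703,111.1916821
15.2,148.933,0.0346521,4.77703,153.7446821
15.861,132.932,0.0366484,4.52399,137.4926384
15.861,154.201,0.0366484,4.52399,158.7616384
16,150.65,0.0370663,4.47298,155.1600463
17,128.136,0.0400481,4.12736,132.3034081
18,110,0.0429787,3.81641,113.8593887
19,95.2134,0.0458482,3.53649,98.7957382
20,83.0272,0.0486485,3.2842,86.3600485
21,73.0045,0.051373,3.05643,76.112303
22,64.5771,0.0540169,2.85043,67.4815469
23,57.4349,0.0565763,2.66371,60.1551863
24,51.3381,0.0590488,2.4941,53.8912488
25,46.0992,0.0614327,2.33969,48.5003227
26,41.5701,0.0637273,2.19879,43.8326173
27,37.6326,0.0659324,2.06993,39.7684624
28,34.1915,0.0680488,1.95183,36.2113788
29,31.1699,0.0700773,1.84334,33.0833173
30,28.5045,0.0720196,1.74347,30.3199896
31,26.1107,0.0738772,1.65136,27.8359372
32,23.9846,0.0756524,1.56623,25.6264824
33,22.0894,0.0773473,1.4874,23.6541473
34,20.3939,0.0789642,1.41428,21.8871442
35,18.8722,0.0805058,1.34633,20.2990358
36,17.5023,0.0819745,1.28309,18.8673645
37,16.2653,0.083373,1.22413,17.572803
38,15.1453,0.0847039,1.16907,16.3990739
39,14.1287,0.0859697,1.11759,15.3322597
40,13.2034,0.0871731,1.06938,14.3599531
41,12.3513,0.0883165,1.02418,13.4637965
42,11.5728,0.0894026,0.98174,12.6439426
43,10.86,0.0904336,0.941842,11.8922756
44,10.206,0.091412,0.904289,11.201701
45,9.60477,0.0923401,0.868903,10.5660131
46,9.05103,0.09322,0.835522,9.979772
47,8.54012,0.0940539,0.803999,9.4381729
48,8.06791,0.0948439,0.774198,8.9369519
49,7.63075,0.0955919,0.745999,8.4723409
50,7.22541,0.0962999,0.71929,8.0409999
51,6.84716,0.0969696,0.693967,7.6380966
52,6.4955,0.0976028,0.669939,7.2630418
53,6.16808,0.0982013,0.647118,6.9133993
54,5.86284,0.0987664,0.625427,6.5870334
55,5.57789,0.0992999,0.604792,6.2819819
56,5.31156,0.0998031,0.585146,5.9965091
57,5.06233,0.100278,0.566429,5.729037
58,4.82882,0.100724,0.548583,5.478127
59,4.60981,0.101145,0.531554,5.242509
60,4.40416,0.10154,0.515296,5.020996
61,4.21046,0.101912,0.499761,4.812133
62,4.02821,0.102261,0.484909,4.61538
63,3.85659,0.102588,0.4707,4.429878
64,3.69481,0.102894,0.457098,4.254802
65,3.54217,0.103181,0.44407,4.089421
66,3.39802,0.103448,0.431583,3.933051
67,3.26178,0.103698,0.419609,3.785087
68,3.1329,0.10393,0.40812,3.64495
69,3.01088,0.104146,0.39709,3.512116
70,2.89527,0.104346,0.386496,3.386112
71,2.78564,0.104531,0.376314,3.266485
72,2.68162,0.104702,0.366525,3.152847
73,2.58283,0.104859,0.357109,3.044798
74,2.48895,0.105003,0.348046,2.941999
75,2.39968,0.105134,0.33932,2.844134
76,2.31473,0.105254,0.330914,2.750898
77,2.23384,0.105362,0.322813,2.662015
78,2.15676,0.105459,0.315003,2.577222
79,2.08328,0.105546,0.307469,2.496295
80,2.01318,0.105623,0.3002,2.419003
81,1.9464,0.10569,0.293182,2.345272
82,1.88262,0.105748,0.286405,2.274773
83,1.82166,0.105798,0.279858,2.207316
84,1.76337,0.105839,0.27353,2.142739
85,1.7076,0.105872,0.267413,2.080885
86,1.65422,0.105898,0.261496,2.021614
87,1.6031,0.105916,0.255772,1.964788
88,1.55411,0.105927,0.250231,1.910268
88.005,1.55387,0.105927,0.250204,1.910001
88.005,7.32687,0.105927,0.250204,7.683001
89,7.11484,0.105932,0.244867,7.465639
90,6.9102,0.10593,0.239672,7.255802
91,6.7136,0.105922,0.234639,7.054161
92,6.52466,0.105909,0.229761,6.86033
93,6.343,0.105889,0.225032,6.673921
94,6.16825,0.105865,0.220447,6.494562
95,6.00009,0.105835,0.215999,6.321924
96,5.83821,0.105801,0.211683,6.155694
97,5.6823,0.105761,0.207494,5.995555
98,5.5321,0.105718,0.203427,5.841245
99,5.38733,0.10567,0.199477,5.692477
100,5.24774,0.105618,0.195641,5.548999
101,5.11347,0.105561,0.191913,5.410944
102,4.9839,0.105502,0.18829,5.277692
103,4.85884,0.105438,0.184767,5.149045
104,4.73807,0.105371,0.181342,5.024783
105,4.62143,0.105301,0.17801,4.904741
106,4.50871,0.105228,0.174769,4.788707
107,4.39977,0.105152,0.171614,4.676536
108,4.29444,0.105073,0.168544,4.568057
109,4.19256,0.104991,0.165554,4.463105
110,4.094,0.104906,0.162643,4.361549
111,3.99861,0.104819,0.159808,4.263237
112,3.90628,0.10473,0.157045,4.168055
113,3.81687,0.104638,0.154353,4.075861
114,3.73026,0.104544,0.151729,3.986533
115,3.64636,0.104449,0.149171,3.89998
116,3.56504,0.104351,0.146677,3.816068
117,3.48621,0.104251,0.144244,3.734705
118,3.40977,0.104149,0.141871,3.65579
119,3.33563,0.104046,0.139555,3.579231
120,3.26371,0.103941,0.137296,3.504947
121,3.19391,0.103834,0.13509,3.432834
122,3.12616,0.103726,0.132937,3.362823
123,3.06039,0.103616,0.130835,3.294841
124,2.99651,0.103505,0.128781,3.228796
125,2.93447,0.103393,0.126776,3.164639
126,2.87419,0.103279,0.124816,3.102285
127,2.8156,0.103165,0.122902,3.041667
128,2.75866,0.103049,0.121031,2.98274
129,2.7033,0.102932,0.119202,2.925434
130,2.64947,0.102814,0.117414,2.869698
131,2.59711,0.102696,0.115665,2.815471
132,2.54617,0.102576,0.113956,2.762702
133,2.4966,0.102455,0.112283,2.711338
134,2.44835,0.102334,0.110647,2.661331
135,2.40139,0.102212,0.109046,2.612648
136,2.35567,0.102089,0.10748,2.565239
137,2.31114,0.101965,0.105947,2.519052
138,2.26777,0.101841,0.104446,2.474057
139,2.22551,0.101716,0.102977,2.430203
140,2.18434,0.101591,0.101538,2.387469
141,2.14421,0.101465,0.100129,2.345804
142,2.1051,0.101339,0.0987494,2.3051884
143,2.06697,0.101212,0.0973977,2.2655797
144,2.02979,0.101085,0.0960735,2.2269485
145,1.99352,0.100957,0.0947759,2.1892529
146,1.95815,0.100829,0.0935043,2.1524833
147,1.92364,0.1007,0.0922581,2.1165981
148,1.88996,0.100572,0.0910364,2.0815684
149,1.8571,0.100443,0.0898387,2.0473817
150,1.82502,0.100313,0.0886644,2.0139974
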