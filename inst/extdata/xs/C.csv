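# symbol=C Z=6 atomic_mass=12.0110 k_edge_keV=NA
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,3045.75,0.0667591,1.06992,3046.8866791
2,346.296,0.126453,0.802401,347.224854
3,97.0729,0.155159,0.564155,97.792214
4,39.3732,0.169323,0.399373,39.941896
5,19.5533,0.176916,0.292075,20.022291
6,11.037,0.181257,0.221262,11.439519
7,6.80547,0.183836,0.172861,7.162167
8,4.47665,0.185386,0.138535,4.800571
9,3.09387,0.186297,0.113375,3.393542
10,2.22318,0.186794,0.0944129,2.5043869
11,1.63667,0.187009,0.0797806,1.9034596
12,1.23746,0.187029,0.0682622,1.4927512
13,0.956807,0.186908,0.0590388,1.2027538
14,0.754052,0.186684,0.0515432,0.9922792
15,0.60411,0.186384,0.0453726,0.8358666
16,0.492192,0.186026,0.0402345,0.7184525
17,0.406022,0.185624,0.0359125,0.6275585
18,0.338643,0.185188,0.0322439,0.5560749
19,0.285232,0.184727,0.0291043,0.4990633
20,0.24237,0.184244,0.0263975,0.4530115
21,0.207379,0.183746,0.0240479,0.4151729
22,0.178732,0.183236,0.0219959,0.3839639
23,0.155064,0.182717,0.0201935,0.3579745
24,0.135346,0.18219,0.0186021,0.3361381
25,0.118793,0.181659,0.0171903,0.3176423
26,0.1048,0.181123,0.0159322,0.3018552
27,0.0928928,0.180585,0.0148063,0.2882841
28,0.0827008,0.180046,0.0137949,0.2765417
29,0.0739279,0.179505,0.0128831,0.266316
30,0.0663374,0.178965,0.0120582,0.2573606
31,0.059886,0.178425,0.0113096,0.2496206
32,0.0542379,0.177887,0.0106283,0.2427532
33,0.0492725,0.17735,0.0100064,0.2366289
34,0.0448901,0.176814,0.00943725,0.23114135
35,0.0410081,0.176281,0.00891509,0.22620419
36,0.0375574,0.17575,0.00843489,0.22174229
37,0.03448,0.175221,0.00799231,0.21769331
38,0.031727,0.174695,0.00758352,0.21400552
39,0.029257,0.174172,0.00720519,0.21063419
40,0.0270347,0.173652,0.00685436,0.20754106
41,0.0250749,0.173135,0.00652845,0.20473835
42,0.0232994,0.172621,0.00622517,0.20214557
43,0.0216871,0.17211,0.00594246,0.19973956
44,0.0202196,0.171602,0.00567852,0.19750012
45,0.0188812,0.171098,0.00543172,0.19541092
46,0.0176579,0.170597,0.00520062,0.19345552
47,0.0165376,0.170099,0.00498392,0.19162052
48,0.0155098,0.169605,0.00478045,0.18989525
49,0.0145652,0.169114,0.00458915,0.18826835
50,0.0136955,0.168626,0.00440908,0.18673058
51,0.0129377,0.168142,0.00423937,0.18531907
52,0.0122353,0.167661,0.00407925,0.18397555
53,0.0115834,0.167183,0.00392802,0.18269442
54,0.0109774,0.166709,0.00378502,0.18147142
55,0.0104134,0.166238,0.00364967,0.18030107
56,0.00988781,0.165771,0.00352144,0.17918025
57,0.00939733,0.165307,0.00339983,0.17810416
58,0.00893908,0.164846,0.0032844,0.17706948
59,0.00851046,0.164389,0.00317474,0.1760742
60,0.00810907,0.163934,0.00307048,0.17511355
61,0.00773374,0.163483,0.00297125,0.17418799
62,0.00738146,0.163036,0.00287675,0.17329421
63,0.00705049,0.162591,0.00278668,0.17242817
64,0.00673922,0.16215,0.00270077,0.17158999
65,0.00644621,0.161712,0.00261876,0.17077697
66,0.00617012,0.161276,0.00254042,0.16998654
67,0.00590975,0.160845,0.00246554,0.16922029
68,0.00566398,0.160416,0.00239392,0.1684739
69,0.0054318,0.15999,0.00232537,0.16774717
70,0.00521227,0.159567,0.00225972,0.16703899
71,0.00500455,0.159147,0.00219681,0.16634836
72,0.00480783,0.15873,0.00213648,0.16567431
73,0.00462141,0.158317,0.0020786,0.16501701
74,0.0044446,0.157906,0.00202304,0.16437364
75,0.0042768,0.157498,0.00196967,0.16374447
76,0.00411743,0.157092,0.00191839,0.16312782
77,0.00396597,0.15669,0.00186907,0.16252504
78,0.00382193,0.15629,0.00182164,0.16193357
79,0.00368485,0.155894,0.00177598,0.16135483
80,0.00355433,0.1555,0.00173202,0.16078635
81,0.00343279,0.155108,0.00168967,0.16023046
82,0.00331682,0.15472,0.00164885,0.15968567
83,0.0032061,0.154334,0.00160949,0.15914959
84,0.00310034,0.153951,0.00157152,0.15862286
85,0.00299926,0.15357,0.00153488,0.15810414
86,0.0029026,0.153192,0.0014995,0.1575941
87,0.00281012,0.152817,0.00146533,0.15709245
88,0.0027216,0.152444,0.00143232,0.15659792
89,0.00263681,0.152074,0.0014004,0.15611121
90,0.00255557,0.151706,0.00136954,0.15563111
91,0.00247769,0.151341,0.00133969,0.15515838
92,0.002403,0.150978,0.00131081,0.15469181
93,0.00233133,0.150617,0.00128284,0.15423117
94,0.00226253,0.150259,0.00125576,0.15377729
95,0.00219645,0.149904,0.00122953,0.15332998
96,0.00213297,0.14955,0.00120411,0.15288708
97,0.00207195,0.149199,0.00117947,0.15245042
98,0.00201328,0.148851,0.00115558,0.15201986
99,0.00195684,0.148504,0.00113241,0.15159325
100,0.00190252,0.14816,0.00110992,0.15117244
101,0.00185716,0.147818,0.0010881,0.15076326
102,0.00181332,0.147479,0.00106691,0.15035923
103,0.00177092,0.147141,0.00104634,0.14995826
104,0.00172991,0.146806,0.00102636,0.14956227
105,0.00169022,0.146473,0.00100694,0.14917016
106,0.00165181,0.146142,0.000988067,0.148781877
107,0.00161462,0.145813,0.00096972,0.14839734
108,0.00157861,0.145487,0.000951879,0.148017489
109,0.00154371,0.145162,0.000934525,0.147640235
110,0.0015099,0.144839,0.000917642,0.147266542
111,0.00147712,0.144519,0.000901211,0.146897331
112,0.00144534,0.1442,0.000885217,0.146530557
113,0.00141452,0.143884,0.000869645,0.146168165
114,0.00138462,0.143569,0.00085448,0.1458081
115,0.0013556,0.143257,0.000839708,0.145452308
116,0.00132743,0.142946,0.000825316,0.145098746
117,0.00130009,0.142637,0.00081129,0.14474838
118,0.00127353,0.14233,0.000797618,0.144401148
119,0.00124773,0.142025,0.000784289,0.144057019
120,0.00122266,0.141722,0.00077129,0.14371595
121,0.0011983,0.141421,0.000758612,0.143377912
122,0.00117462,0.141122,0.000746244,0.143042864
123,0.0011516,0.140824,0.000734176,0.142709776
124,0.00112921,0.140528,0.000722397,0.142379607
125,0.00110742,0.140234,0.0007109,0.14205232
126,0.00108623,0.139942,0.000699675,0.141727905
127,0.0010656,0.139652,0.000688713,0.141406313
128,0.00104553,0.139363,0.000678007,0.141086537
129,0.00102598,0.139076,0.000667549,0.140769529
130,0.00100695,0.138791,0.00065733,0.14045528
131,0.000988406,0.138507,0.000647344,0.14014275
132,0.000970345,0.138225,0.000637584,0.139832929
133,0.000952746,0.137945,0.000628042,0.139525788
134,0.000935595,0.137666,0.000618713,0.139220308
135,0.000918877,0.137389,0.000609591,0.138917468
136,0.000902578,0.137114,0.000600668,0.138617246
137,0.000886684,0.13684,0.00059194,0.138318624
138,0.000871182,0.136567,0.0005834,0.138021582
139,0.000856061,0.136297,0.000575044,0.137728105
140,0.000841307,0.136028,0.000566866,0.137436173
141,0.000826911,0.13576,0.000558861,0.137145772
142,0.000812859,0.135494,0.000551024,0.136857883
143,0.000799143,0.135229,0.000543351,0.136571494
144,0.000785751,0.134966,0.000535837,0.136287588
145,0.000772674,0.134705,0.000528477,0.136006151
146,0.000759902,0.134444,0.000521268,0.13572517
147,0.000747427,0.134186,0.000514206,0.135447633
148,0.000735238,0.133929,0.000507286,0.135171524
149,0.000723329,0.133673,0.000500504,0.134896833
150,0.00071169,0.133418,0.000493858,0.134623548
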