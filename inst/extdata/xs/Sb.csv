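# symbol=Sb Z=51 atomic_mass=121.7600 k_edge_keV=30.491
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,21507.3,0.000996814,8.45609,21515.757086814
2,3547.39,0.00340724,8.16374,3555.55714724
3,1236.15,0.00689041,7.71662,1243.87351041
4,585.101,0.0112047,7.16339,592.2755947
4.132,537.737,0.0118248,7.08516,544.8339848
4.132,1075.47,0.0118248,7.08516,1082.5669848
4.38,920.475,0.0130174,6.936,927.4240174
4.38,1288.67,0.0130174,6.936,1295.6190174
4.698,1068.73,0.014595,6.74148,1075.486075
4.698,1068.73,0.014595,6.74148,1075.486075
5,904.953,0.0161387,6.55455,911.5236887
6,556.176,0.021504,5.93377,562.131274
7,368.523,0.0271362,5.33347,373.8836062
8,258.004,0.0328957,4.77424,262.8111357
9,188.386,0.0386679,4.26667,192.6913379
10,142.192,0.0443614,3.81404,146.0504014
11,110.245,0.0499061,3.41498,113.7098861
12,87.39,0.0552508,3.0655,90.5107508
13,70.5744,0.0603596,2.76042,73.3951796
14,57.9047,0.0652098,2.49432,60.4642298
15,48.1629,0.0697888,2.26198,50.4946688
16,40.5392,0.0740922,2.05868,42.6719722
17,34.4808,0.0781213,1.88026,36.4391813
18,29.6005,0.0818822,1.72315,31.4055322
19,25.6215,0.0853839,1.58428,27.2911639
20,22.3422,0.0886376,1.46108,23.8919176
21,19.6133,0.0916557,1.35136,21.0563157
22,17.3224,0.0944514,1.25328,18.6701314
23,15.3838,0.0970382,1.1653,16.6461382
24,13.7313,0.0994294,1.0861,14.9168294
25,12.3133,0.101638,1.01457,13.429508
26,11.0891,0.103677,0.949769,12.142546
27,10.0262,0.105557,0.89088,11.022637
28,9.09838,0.107291,0.837217,10.042888
29,8.28463,0.108888,0.788186,9.181704
30,7.56767,0.110359,0.743272,8.421301
30.491,7.24665,0.111038,0.722589,8.080277
30.491,39.2189,0.111038,0.722589,40.052527
31,37.492,0.111713,0.702031,38.305744
32,34.3902,0.112959,0.664077,35.167236
33,31.6289,0.114105,0.629073,32.372078
34,29.1622,0.115157,0.596723,29.87408
35,26.9511,0.116123,0.566767,27.63399
36,24.9632,0.11701,0.538978,25.619188
37,23.1704,0.117822,0.513152,23.801374
38,21.5492,0.118566,0.489111,22.156877
39,20.0792,0.119246,0.466695,20.665141
40,18.743,0.119867,0.445763,19.30863
41,17.5255,0.120433,0.426188,18.072121
42,16.4136,0.120948,0.407855,16.942403
43,15.396,0.121416,0.390663,15.908079
44,14.4628,0.12184,0.37452,14.95916
45,13.6052,0.122223,0.359343,14.086766
46,12.8157,0.122567,0.345057,13.283324
47,12.0875,0.122876,0.331595,12.541971
48,11.4147,0.123152,0.318895,11.856747
49,10.7922,0.123397,0.306901,11.222498
50,10.2151,0.123613,0.295562,10.634275
51,9.67947,0.123802,0.284831,10.088103
52,9.18149,0.123966,0.274668,9.580124
53,8.7179,0.124107,0.265031,9.107038
54,8.28574,0.124225,0.255887,8.665852
55,7.88235,0.124323,0.247202,8.253875
56,7.50535,0.124402,0.238947,7.868699
57,7.15258,0.124463,0.231093,7.508136
58,6.8221,0.124507,0.223616,7.170223
59,6.51216,0.124536,0.216491,6.853187
60,6.22115,0.124549,0.209698,6.555397
61,5.94765,0.124549,0.203217,6.275416
62,5.69032,0.124536,0.197027,6.011883
63,5.44799,0.124511,0.191114,5.763615
64,5.21955,0.124474,0.185459,5.529483
65,5.00401,0.124426,0.18005,5.308486
66,4.80046,0.124369,0.174871,5.0997
67,4.60807,0.124302,0.16991,4.902282
68,4.42607,0.124227,0.165156,4.715453
69,4.25376,0.124143,0.160596,4.538499
70,4.09049,0.124051,0.15622,4.370761
71,3.93568,0.123952,0.15202,4.211652
72,3.78877,0.123846,0.147985,4.060601
73,3.64925,0.123734,0.144107,3.917091
74,3.51667,0.123615,0.140378,3.780663
75,3.39059,0.123491,0.136791,3.650872
76,3.27061,0.123362,0.133338,3.52731
77,3.15637,0.123228,0.130014,3.409612
78,3.04751,0.123089,0.126811,3.29741
79,2.94372,0.122945,0.123724,3.190389
80,2.84471,0.122798,0.120747,3.088255
81,2.75019,0.122647,0.117876,2.990713
82,2.65992,0.122492,0.115105,2.897517
83,2.57365,0.122333,0.11243,2.808413
84,2.49117,0.122172,0.109847,2.723189
85,2.41225,0.122008,0.10735,2.641608
86,2.33672,0.12184,0.104938,2.563498
87,2.26438,0.121671,0.102605,2.488656
88,2.19508,0.121499,0.100349,2.416928
89,2.12864,0.121324,0.0981653,2.3481293
90,2.06492,0.121148,0.096052,2.28212
91,2.00378,0.120969,0.0940057,2.2187547
92,1.94509,0.120789,0.0920237,2.1579027
93,1.88872,0.120607,0.0901033,2.0994303
94,1.83457,0.120424,0.0882421,2.0432361
95,1.78252,0.120239,0.0864375,1.9891965
96,1.73247,0.120053,0.0846874,1.9372104
97,1.68431,0.119865,0.0829896,1.8871646
98,1.63798,0.119677,0.081342,1.838999
99,1.59336,0.119487,0.0797427,1.7925897
100,1.55039,0.119297,0.0781898,1.7478768
101,1.509,0.119105,0.0766816,1.7047866
102,1.46909,0.118913,0.0752164,1.6632194
103,1.43062,0.118721,0.0737925,1.6231335
104,1.39351,0.118527,0.0724085,1.5844455
105,1.35771,0.118333,0.0710628,1.5471058
106,1.32315,0.118139,0.0697541,1.5110431
107,1.28979,0.117944,0.068481,1.476215
108,1.25756,0.117749,0.0672423,1.4425513
109,1.22643,0.117553,0.0660367,1.4100197
110,1.19634,0.117357,0.0648631,1.3785601
111,1.16725,0.117161,0.0637203,1.3481313
112,1.13912,0.116965,0.0626074,1.3186924
113,1.11191,0.116769,0.0615231,1.2902021
114,1.08558,0.116572,0.0604667,1.2626187
115,1.06009,0.116376,0.0594371,1.2359031
116,1.03542,0.116179,0.0584335,1.2100325
117,1.01153,0.115983,0.057455,1.184968
118,0.988378,0.115787,0.0565007,1.1606657
119,0.96595,0.115591,0.0555699,1.1371109
120,0.944212,0.115395,0.0546618,1.1142688
121,0.923137,0.115199,0.0537757,1.0921117
122,0.9027,0.115003,0.0529109,1.0706139
123,0.882877,0.114808,0.0520667,1.0497517
124,0.863645,0.114612,0.0512424,1.0294994
125,0.844981,0.114417,0.0504375,1.0098355
126,0.826865,0.114223,0.0496513,0.9907393
127,0.809275,0.114028,0.0488833,0.9721863
128,0.792193,0.113834,0.0481329,0.9541599
129,0.775601,0.113641,0.0473996,0.9366416
130,0.75948,0.113448,0.0466828,0.9196108
131,0.743814,0.113255,0.0459821,0.9030511
132,0.728587,0.113062,0.045297,0.886946
133,0.713782,0.11287,0.0446271,0.8712791
134,0.699386,0.112679,0.0439718,0.8560368
135,0.685385,0.112488,0.0433309,0.8412039
136,0.671764,0.112297,0.0427037,0.8267647
137,0.65851,0.112107,0.0420901,0.8127071
138,0.645611,0.111917,0.0414895,0.7990175
139,0.633056,0.111728,0.0409017,0.7856857
140,0.620832,0.111539,0.0403262,0.7726972
141,0.608928,0.111351,0.0397628,0.7600418
142,0.597335,0.111163,0.039211,0.747709
143,0.586041,0.110976,0.0386706,0.7356876
144,0.575038,0.11079,0.0381412,0.7239692
145,0.564315,0.110604,0.0376226,0.7125416
146,0.553863,0.110418,0.0371145,0.7013955
147,0.543675,0.110233,0.0366166,0.6905246
148,0.533741,0.110049,0.0361286,0.6799186
149,0.524054,0.109865,0.0356503,0.6695693
150,0.514605,0.109682,0.0351813,0.6594683
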