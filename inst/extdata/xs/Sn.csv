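# symbol=Sn Z=50 atomic_mass=118.7100 k_edge_keV=29.2
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,20524,0.00104406,8.33441,20532.33545406
2,3385.19,0.00356657,8.04031,3393.23387657
3,1179.63,0.00720627,7.59131,1187.22851627
3.929,584.963,0.0113627,7.07881,592.0531727
3.929,1169.93,0.0113627,7.07881,1177.0201727
4,1115.3,0.0117055,7.0371,1122.3488055
4.156,1007,0.0124699,6.94455,1013.9570199
4.156,1409.79,0.0124699,6.94455,1416.7470199
4.465,1164.12,0.0140264,6.75811,1170.8921364
4.465,1164.12,0.0140264,6.75811,1170.8921364
5,860.537,0.0168387,6.42896,866.9827987
6,528.878,0.0224058,5.81083,534.7112358
7,350.435,0.0282332,5.215,355.6782332
8,245.34,0.0341745,4.66163,250.0358045
9,179.14,0.0401105,4.1608,183.3409105
10,135.213,0.0459476,3.71535,138.9742976
11,104.834,0.0516149,3.32351,108.2091249
12,83.1008,0.0570613,2.98102,86.1388813
13,67.1105,0.0622523,2.68255,69.8553023
14,55.0627,0.0671665,2.42258,57.5524465
15,45.799,0.0717934,2.19586,48.0666534
16,38.5495,0.0761303,1.99768,40.6233103
17,32.7884,0.0801806,1.8239,34.6924806
18,28.1476,0.0839522,1.67098,29.9025322
19,24.3639,0.0874556,1.53589,25.9872456
20,21.2456,0.0907037,1.41611,22.7524137
21,18.6506,0.0937103,1.30948,20.0537903
22,16.4722,0.0964895,1.21421,17.7828995
23,14.6287,0.0990559,1.12876,15.8565159
24,13.0574,0.101424,1.05187,14.210694
25,11.709,0.103606,0.982445,12.795051
26,10.5449,0.105618,0.919559,11.570077
27,9.53406,0.107469,0.862427,10.503956
28,8.65182,0.109173,0.810376,9.571369
29,7.87801,0.110741,0.762825,8.751576
29.2,7.73476,0.111039,0.75381,8.599609
29.2,42.1235,0.111039,0.75381,42.988349
30,39.1378,0.112181,0.719276,39.969257
31,35.7983,0.113505,0.679294,36.591099
32,32.8366,0.114721,0.642505,33.593826
33,30.2001,0.115837,0.60858,30.924517
34,27.8448,0.11686,0.577232,28.538892
35,25.7336,0.117798,0.548207,26.399605
36,23.8354,0.118656,0.521285,24.475341
37,22.1237,0.119441,0.496269,22.73941
38,20.5757,0.120158,0.472984,21.168842
39,19.1721,0.120813,0.451275,19.744188
40,17.8963,0.121408,0.431006,18.448714
41,16.7338,0.12195,0.412052,17.267802
42,15.6721,0.122442,0.394303,16.188845
43,14.7005,0.122886,0.37766,15.201046
44,13.8094,0.123288,0.362034,14.294722
45,12.9906,0.123649,0.347344,13.461593
46,12.2367,0.123973,0.333518,12.694191
47,11.5414,0.124261,0.320491,11.986152
48,10.8991,0.124518,0.308201,11.331819
49,10.3046,0.124744,0.296596,10.72594
50,9.75366,0.124941,0.285625,10.164226
51,9.2422,0.125113,0.275244,9.642557
52,8.76672,0.12526,0.265412,9.157392
53,8.32407,0.125384,0.256091,8.705545
54,7.91143,0.125486,0.247246,8.284162
55,7.52627,0.125569,0.238846,7.890685
56,7.16629,0.125633,0.230862,7.522785
57,6.82946,0.125679,0.223267,7.178406
58,6.51391,0.125709,0.216036,6.855655
59,6.21797,0.125724,0.209147,6.552841
60,5.94011,0.125724,0.202578,6.268412
61,5.67896,0.125711,0.196311,6.000982
62,5.43326,0.125686,0.190327,5.749273
63,5.20187,0.125648,0.18461,5.512128
64,4.98375,0.1256,0.179143,5.288493
65,4.77795,0.125541,0.173914,5.077405
66,4.5836,0.125473,0.168907,4.87798
67,4.3999,0.125395,0.164112,4.689407
68,4.22612,0.125309,0.159516,4.510945
69,4.06159,0.125215,0.155109,4.341914
70,3.9057,0.125114,0.15088,4.181694
71,3.75788,0.125005,0.14682,4.029705
72,3.61761,0.12489,0.14292,3.88542
73,3.4844,0.124769,0.139173,3.748342
74,3.35781,0.124641,0.135569,3.61802
75,3.23742,0.124509,0.132103,3.494032
76,3.12286,0.124371,0.128766,3.375997
77,3.01378,0.124229,0.125553,3.263562
78,2.90984,0.124082,0.122459,3.156381
79,2.81074,0.123931,0.119476,3.054147
80,2.7162,0.123776,0.1166,2.956576
81,2.62595,0.123617,0.113826,2.863393
82,2.53976,0.123455,0.111148,2.774363
83,2.45739,0.12329,0.108564,2.689244
84,2.37863,0.123122,0.106068,2.60782
85,2.30328,0.122951,0.103656,2.529887
86,2.23116,0.122777,0.101325,2.455262
87,2.16209,0.122601,0.0990718,2.3837628
88,2.09591,0.122423,0.0968919,2.3152249
89,2.03248,0.122242,0.0947828,2.2495048
90,1.97163,0.12206,0.0927413,2.1864313
91,1.91326,0.121876,0.0907646,2.1259006
92,1.85722,0.12169,0.08885,2.06776
93,1.8034,0.121503,0.086995,2.011898
94,1.75169,0.121314,0.0851971,1.9582011
95,1.70199,0.121124,0.083454,1.906568
96,1.6542,0.120932,0.0817636,1.8568956
97,1.60823,0.12074,0.0801237,1.8090937
98,1.56398,0.120546,0.0785323,1.7630583
99,1.52138,0.120352,0.0769876,1.7187196
100,1.48036,0.120157,0.0754878,1.6760048
101,1.44083,0.11996,0.0740311,1.6348211
102,1.40273,0.119764,0.0726159,1.5951099
103,1.36599,0.119566,0.0712408,1.5567968
104,1.33056,0.119369,0.0699041,1.5198331
105,1.29638,0.11917,0.0686044,1.4841544
106,1.26338,0.118972,0.0673405,1.4496925
107,1.23152,0.118773,0.066111,1.416404
108,1.20075,0.118573,0.0649147,1.3842377
109,1.17102,0.118374,0.0637505,1.3531445
110,1.14229,0.118174,0.0626171,1.3230811
111,1.11452,0.117974,0.0615135,1.2940075
112,1.08766,0.117774,0.0604387,1.2658727
113,1.06168,0.117574,0.0593917,1.2386457
114,1.03654,0.117374,0.0583715,1.2122855
115,1.0122,0.117174,0.0573773,1.1867513
116,0.988645,0.116974,0.0564081,1.1620271
117,0.96583,0.116774,0.0554632,1.1380672
118,0.943728,0.116574,0.0545417,1.1148437
119,0.922313,0.116375,0.0536429,1.0923309
120,0.901557,0.116175,0.0527661,1.0704981
121,0.881434,0.115976,0.0519104,1.0493204
122,0.861921,0.115777,0.0510754,1.0287734
123,0.842993,0.115578,0.0502602,1.0088312
124,0.82463,0.11538,0.0494643,0.9894743
125,0.806809,0.115182,0.0486871,0.9706781
126,0.789511,0.114984,0.047928,0.952423
127,0.772716,0.114787,0.0471864,0.9346894
128,0.756406,0.11459,0.0464619,0.9174579
129,0.740563,0.114394,0.0457538,0.9007108
130,0.725171,0.114197,0.0450617,0.8844297
131,0.710212,0.114002,0.0443852,0.8685992
132,0.695673,0.113807,0.0437237,0.8532037
133,0.681537,0.113612,0.0430769,0.8382259
134,0.667792,0.113417,0.0424443,0.8236533
135,0.654423,0.113224,0.0418254,0.8094724
136,0.641417,0.11303,0.0412199,0.7956669
137,0.628762,0.112838,0.0406275,0.7822275
138,0.616446,0.112645,0.0400476,0.7691386
139,0.604458,0.112454,0.0394801,0.7563921
140,0.592786,0.112262,0.0389245,0.7439725
141,0.58142,0.112072,0.0383805,0.7318725
142,0.57035,0.111882,0.0378478,0.7200798
143,0.559567,0.111692,0.037326,0.708585
144,0.54906,0.111503,0.036815,0.697378
145,0.538822,0.111315,0.0363143,0.6864513
146,0.528842,0.111127,0.0358238,0.6757928
147,0.519114,0.11094,0.0353431,0.6653971
148,0.509629,0.110753,0.0348719,0.6552539
149,0.500379,0.110567,0.0344101,0.6453561
150,0.491358,0.110382,0.0339574,0.6356974
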