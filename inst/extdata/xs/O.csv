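# symbol=O Z=8 atomic_mass=15.9990 k_edge_keV=NA
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,7678.45,0.0433542,1.47098,7679.9643342
2,873.025,0.097696,1.17636,874.299056
3,244.725,0.132122,0.878427,245.735549
4,99.2613,0.152069,0.648225,100.061594
5,49.2947,0.16391,0.486444,49.945054
6,27.8247,0.171237,0.374542,28.370479
7,17.1568,0.175934,0.29586,17.628594
8,11.2858,0.179022,0.239052,11.703874
9,7.79977,0.181077,0.196903,8.17775
10,5.60471,0.182445,0.164841,5.951996
11,4.15639,0.183338,0.139917,4.479645
12,3.16362,0.183894,0.120175,3.467689
13,2.46119,0.184204,0.10428,2.749674
14,1.9507,0.184333,0.0913024,2.2263354
15,1.5711,0.184324,0.0805735,1.8359975
16,1.28203,0.18421,0.0716064,1.5378464
17,1.05913,0.184014,0.0640385,1.3071825
18,0.884592,0.183753,0.0575954,1.1259404
19,0.746046,0.183442,0.0520666,0.9815546
20,0.634722,0.18309,0.0472882,0.8651002
21,0.544574,0.182705,0.0431315,0.7704105
22,0.470572,0.182295,0.039494,0.692361
23,0.409275,0.181863,0.0362934,0.6274314
24,0.358084,0.181414,0.0334628,0.5729608
25,0.315009,0.180951,0.0309479,0.5269079
26,0.278513,0.180477,0.0287037,0.4876937
27,0.247392,0.179994,0.026693,0.454079
28,0.220698,0.179505,0.0248846,0.4250876
29,0.197674,0.17901,0.0232526,0.3999366
30,0.177715,0.17851,0.0217748,0.3779998
31,0.160482,0.178008,0.0204325,0.3589225
32,0.145391,0.177503,0.0192098,0.3421038
33,0.132119,0.176996,0.0180929,0.3272079
34,0.120403,0.176489,0.0170701,0.3139621
35,0.110021,0.175982,0.016131,0.302134
36,0.10079,0.175475,0.015267,0.291532
37,0.0925559,0.174968,0.0144701,0.281994
38,0.0851877,0.174463,0.0137337,0.2733844
39,0.0785752,0.173959,0.0130518,0.265586
40,0.0726245,0.173456,0.0124193,0.2584998
41,0.0673301,0.172955,0.0118314,0.2521165
42,0.0625357,0.172457,0.0112841,0.2462768
43,0.0581838,0.17196,0.0107737,0.2409175
44,0.0542245,0.171466,0.0102971,0.2359876
45,0.0506148,0.170974,0.00985123,0.23144003
46,0.047317,0.170484,0.00943362,0.22723462
47,0.0442981,0.169997,0.0090419,0.223337
48,0.0415295,0.169513,0.008674,0.2197165
49,0.0389858,0.169032,0.00832802,0.21634582
50,0.0366446,0.168553,0.00800226,0.21319986
51,0.034564,0.168077,0.00769519,0.21033619
52,0.0326386,0.167605,0.0074054,0.207649
53,0.0308541,0.167135,0.00713162,0.20512072
54,0.0291978,0.166668,0.0068727,0.2027385
55,0.0276585,0.166204,0.00662759,0.20049009
56,0.0262258,0.165742,0.00639532,0.19836312
57,0.0248909,0.165284,0.00617502,0.19634992
58,0.0236453,0.164829,0.00596587,0.19444017
59,0.0224818,0.164377,0.00576715,0.19262595
60,0.0213936,0.163928,0.00557817,0.19089977
61,0.0203801,0.163482,0.0053983,0.1892604
62,0.01943,0.163039,0.00522697,0.18769597
63,0.0185382,0.162599,0.00506365,0.18620085
64,0.0177005,0.162162,0.00490785,0.18477035
65,0.0169128,0.161727,0.00475912,0.18339892
66,0.0161714,0.161296,0.00461703,0.18208443
67,0.0154729,0.160868,0.00448119,0.18082209
68,0.0148142,0.160442,0.00435125,0.17960745
69,0.0141926,0.16002,0.00422687,0.17843947
70,0.0136055,0.1596,0.00410774,0.17731324
71,0.0130505,0.159183,0.00399357,0.17622707
72,0.0125254,0.158769,0.00388407,0.17517847
73,0.0120283,0.158358,0.00377902,0.17416532
74,0.0115572,0.15795,0.00367816,0.17318536
75,0.0111106,0.157544,0.00358128,0.17223588
76,0.0106868,0.157142,0.00348817,0.17131697
77,0.0102843,0.156742,0.00339863,0.17042493
78,0.00990199,0.156344,0.0033125,0.16955849
79,0.00953845,0.15595,0.00322959,0.16871804
80,0.00919259,0.155558,0.00314975,0.16790034
81,0.00886963,0.155168,0.00307284,0.16711047
82,0.00856177,0.154782,0.0029987,0.16634247
83,0.00826814,0.154398,0.00292721,0.16559335
84,0.00798792,0.154016,0.00285824,0.16486216
85,0.00772034,0.153637,0.00279167,0.16414901
86,0.0074647,0.153261,0.0027274,0.1634531
87,0.00722034,0.152887,0.00266533,0.16277267
88,0.00698663,0.152515,0.00260534,0.16210697
89,0.00676301,0.152146,0.00254736,0.16145637
90,0.00654892,0.15178,0.00249128,0.1608202
91,0.00634386,0.151416,0.00243704,0.1601969
92,0.00614736,0.151054,0.00238454,0.1595859
93,0.00595897,0.150695,0.00233373,0.1589877
94,0.00577828,0.150338,0.00228451,0.15840079
95,0.00560489,0.149984,0.00223684,0.15782573
96,0.00543844,0.149631,0.00219064,0.15726008
97,0.00527859,0.149281,0.00214585,0.15670544
98,0.005125,0.148934,0.00210243,0.15616143
99,0.00497737,0.148588,0.0020603,0.15562567
100,0.00483541,0.148245,0.00201943,0.15509984
101,0.00471145,0.147904,0.00197976,0.15459521
102,0.00459184,0.147565,0.00194125,0.15409809
103,0.00447639,0.147229,0.00190385,0.15360924
104,0.00436491,0.146894,0.00186752,0.15312643
105,0.00425724,0.146562,0.00183222,0.15265146
106,0.00415321,0.146232,0.00179791,0.15218312
107,0.00405266,0.145904,0.00176455,0.15172121
108,0.00395545,0.145578,0.00173211,0.15126556
109,0.00386143,0.145254,0.00170056,0.15081599
110,0.00377048,0.144932,0.00166986,0.15037234
111,0.00368246,0.144612,0.00163998,0.14993444
112,0.00359726,0.144294,0.0016109,0.14950216
113,0.00351477,0.143978,0.00158258,0.14907535
114,0.00343486,0.143664,0.001555,0.14865386
115,0.00335745,0.143352,0.00152814,0.14823759
116,0.00328243,0.143042,0.00150197,0.1478264
117,0.00320971,0.142733,0.00147646,0.14741917
118,0.0031392,0.142427,0.00145159,0.14701779
119,0.00307081,0.142122,0.00142735,0.14662016
120,0.00300446,0.14182,0.00140371,0.14622817
121,0.00294009,0.141519,0.00138065,0.14583974
122,0.0028776,0.14122,0.00135816,0.14545576
123,0.00281694,0.140923,0.00133621,0.14507615
124,0.00275803,0.140627,0.00131479,0.14469982
125,0.00270081,0.140334,0.00129387,0.14432868
126,0.00264522,0.140042,0.00127346,0.14396068
127,0.0025912,0.139752,0.00125352,0.14359672
128,0.0025387,0.139463,0.00123404,0.14323574
129,0.00248765,0.139176,0.00121502,0.14287867
130,0.00243802,0.138891,0.00119643,0.14252545
131,0.00238974,0.138608,0.00117827,0.14217601
132,0.00234277,0.138326,0.00116051,0.14182928
133,0.00229708,0.138046,0.00114315,0.14148623
134,0.0022526,0.137768,0.00112618,0.14114678
135,0.00220931,0.137491,0.00110959,0.1408099
136,0.00216716,0.137216,0.00109335,0.14047651
137,0.00212612,0.136942,0.00107748,0.1401456
138,0.00208614,0.13667,0.00106194,0.13981808
139,0.00204719,0.1364,0.00104674,0.13949393
140,0.00200925,0.136131,0.00103186,0.13917211
141,0.00197227,0.135863,0.0010173,0.13885257
142,0.00193622,0.135597,0.00100304,0.13853626
143,0.00190108,0.135333,0.000989077,0.138223157
144,0.00186681,0.13507,0.000975406,0.137912216
145,0.0018334,0.134808,0.000962016,0.137603416
146,0.0018008,0.134548,0.0009489,0.1372977
147,0.001769,0.13429,0.00093605,0.13699505
148,0.00173797,0.134033,0.000923459,0.136694429
149,0.00170769,0.133777,0.000911121,0.136395811
150,0.00167814,0.133523,0.000899027,0.136100167
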