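# symbol=W Z=74 atomic_mass=183.8400 k_edge_keV=69.525
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,48992.6,0.000444728,11.8378,49004.438244728
2,8080.76,0.00153211,11.5602,8092.32173211
3,2815.89,0.00313426,11.1236,2827.01673426
4,1332.83,0.00517138,10.5621,1343.39727138
5,746.119,0.00757627,9.9148,756.04137627
6,464.448,0.0102881,9.21978,473.6780681
7,311.082,0.0132505,8.51057,319.6058205
8,219.835,0.0164114,7.8136,227.6650114
9,161.845,0.0197232,7.14774,169.0124632
10,123.064,0.0231424,6.52495,129.6120924
10.207,116.68,0.0238599,6.40207,123.1059299
10.207,233.359,0.0238599,6.40207,239.7849299
11,191.102,0.02663,5.95148,197.08011
11.544,167.993,0.0285436,5.6611,173.6826436
11.544,235.19,0.0285436,5.6611,240.8796436
12,212.079,0.0301517,5.4294,217.5385517
12.1,207.431,0.0305045,5.38,212.8415045
12.1,240.62,0.0305045,5.38,246.0305045
13,198.674,0.0336773,4.95782,203.6654973
14,163.007,0.037181,4.53409,167.578271
15,135.583,0.040641,4.15452,139.778161
16,114.122,0.044039,3.81501,117.981049
17,97.0668,0.0473601,3.51141,100.6255701
18,83.3281,0.0505926,3.23975,86.6184426
19,72.1269,0.0537273,2.99633,75.1769573
20,62.8954,0.0567573,2.77782,65.7299773
21,55.1776,0.0596777,2.58126,57.8185377
22,48.7025,0.0624855,2.40401,51.1689955
23,43.2266,0.0651791,2.24379,45.5355691
24,38.5616,0.0677581,2.0986,40.7279581
25,34.5608,0.070223,1.96668,36.597703
26,31.1085,0.0725753,1.84654,33.0276153
27,28.1125,0.074817,1.73683,29.924147
28,25.4987,0.0769508,1.63643,27.2120808
29,23.2074,0.0789796,1.54433,24.8307096
30,21.1894,0.0809068,1.45965,22.7299568
31,19.3802,0.0827358,1.38163,20.8445658
32,17.7758,0.0844702,1.3096,19.1698702
33,16.3476,0.0861138,1.24296,17.6766738
34,15.0718,0.0876702,1.1812,16.3406702
35,13.9284,0.0891433,1.12386,15.1414033
36,12.9003,0.0905367,1.07053,14.0613667
37,11.9732,0.0918539,1.02085,13.0859039
38,11.1349,0.0930986,0.974496,12.2024946
39,10.3748,0.0942742,0.931178,11.4002522
40,9.68398,0.0953839,0.89064,10.6700039
41,9.04932,0.0964311,0.852651,9.9984021
42,8.47009,0.0974186,0.817004,9.3845126
43,7.94028,0.0983496,0.783512,8.8221416
44,7.45467,0.0992268,0.752006,8.3059028
45,7.0087,0.100053,0.722334,7.831087
46,6.59834,0.100831,0.694357,7.393528
47,6.22008,0.101562,0.667949,6.989591
48,5.8708,0.10225,0.642997,6.616047
49,5.54773,0.102896,0.619397,6.270023
50,5.24844,0.103503,0.597052,5.948995
51,4.97019,0.104073,0.575878,5.650141
52,4.71167,0.104607,0.555793,5.37207
53,4.47114,0.105107,0.536726,5.112973
54,4.24705,0.105576,0.518609,4.871235
55,4.038,0.106014,0.501381,4.645395
56,3.84274,0.106423,0.484985,4.434148
57,3.66012,0.106805,0.469369,4.236294
58,3.48914,0.107161,0.454485,4.050786
59,3.32886,0.107492,0.440288,3.87664
60,3.17846,0.1078,0.426737,3.712997
61,3.03706,0.108086,0.413794,3.55894
62,2.90409,0.10835,0.401423,3.413863
63,2.77894,0.108594,0.389591,3.277125
64,2.66102,0.108819,0.378268,3.148107
65,2.54982,0.109026,0.367425,3.026271
66,2.44486,0.109216,0.357036,2.911112
67,2.34571,0.109389,0.347076,2.802175
68,2.25195,0.109546,0.337522,2.699018
69,2.16323,0.109689,0.328352,2.601271
69.525,2.11856,0.109758,0.323685,2.552003
69.525,10.7966,0.109758,0.323685,11.230043
70,10.6041,0.109818,0.319547,11.033465
71,10.214,0.109933,0.311086,10.635019
72,9.84346,0.110035,0.302954,10.256449
73,9.49119,0.110125,0.295132,9.896447
74,9.15606,0.110203,0.287607,9.55387
75,8.83704,0.110271,0.280362,9.227673
76,8.53313,0.110327,0.273384,8.916841
77,8.24345,0.110374,0.266661,8.620485
78,7.96715,0.110411,0.26018,8.337741
79,7.70345,0.11044,0.25393,8.06782
80,7.45164,0.110459,0.247901,7.81
81,7.2144,0.11047,0.242081,7.566951
82,6.98748,0.110474,0.236462,7.334416
83,6.77032,0.110469,0.231034,7.111823
84,6.56239,0.110458,0.22579,6.898638
85,6.3632,0.11044,0.22072,6.69436
86,6.17228,0.110415,0.215817,6.498512
87,5.98919,0.110384,0.211074,6.310648
88,5.81354,0.110348,0.206485,6.130373
89,5.64494,0.110305,0.202042,5.957287
90,5.48303,0.110257,0.19774,5.791027
91,5.32747,0.110205,0.193572,5.631247
92,5.17796,0.110147,0.189534,5.477641
93,5.03419,0.110084,0.18562,5.329894
94,4.89589,0.110018,0.181824,5.187732
95,4.76279,0.109947,0.178143,5.05088
96,4.63465,0.109872,0.174572,4.919094
97,4.51123,0.109793,0.171106,4.792129
98,4.39231,0.10971,0.167741,4.669761
99,4.27769,0.109624,0.164474,4.551788
100,4.16716,0.109535,0.161301,4.437996
101,4.05745,0.109442,0.158218,4.32511
102,3.95167,0.109347,0.155222,4.216239
103,3.84963,0.109248,0.152309,4.111187
104,3.75118,0.109147,0.149477,4.009804
105,3.65615,0.109044,0.146723,3.911917
106,3.5644,0.108937,0.144044,3.817381
107,3.47578,0.108829,0.141437,3.726046
108,3.39015,0.108718,0.138899,3.637767
109,3.3074,0.108605,0.136429,3.552434
110,3.22739,0.10849,0.134023,3.469903
111,3.15002,0.108373,0.131681,3.390074
112,3.07517,0.108255,0.129398,3.312823
113,3.00274,0.108134,0.127174,3.238048
114,2.93263,0.108012,0.125007,3.165649
115,2.86475,0.107889,0.122894,3.095533
116,2.79901,0.107764,0.120834,3.027608
117,2.73532,0.107637,0.118825,2.961782
118,2.67361,0.107509,0.116865,2.897984
119,2.61379,0.10738,0.114953,2.836123
120,2.55579,0.10725,0.113088,2.776128
121,2.49955,0.107119,0.111267,2.717936
122,2.44499,0.106986,0.10949,2.661466
123,2.39206,0.106853,0.107754,2.606667
124,2.34068,0.106719,0.106059,2.553458
125,2.29081,0.106583,0.104404,2.501797
126,2.24238,0.106447,0.102787,2.451614
127,2.19535,0.10631,0.101207,2.402867
128,2.14966,0.106173,0.0996628,2.3554958
129,2.10527,0.106035,0.0981536,2.3094586
130,2.06213,0.105896,0.0966782,2.2647042
131,2.02019,0.105756,0.0952357,2.2211817
132,1.97941,0.105616,0.0938251,2.1788511
133,1.93976,0.105476,0.0924454,2.1376814
134,1.90119,0.105335,0.0910958,2.0976208
135,1.86366,0.105193,0.0897753,2.0586283
136,1.82714,0.105051,0.0884832,2.0206742
137,1.7916,0.104909,0.0872187,1.9837277
138,1.757,0.104766,0.085981,1.947747
139,1.72331,0.104623,0.0847693,1.9127023
140,1.69051,0.10448,0.0835829,1.8785729
141,1.65855,0.104337,0.0824211,1.8453081
142,1.62742,0.104193,0.0812832,1.8128962
143,1.59708,0.104049,0.0801687,1.7812977
144,1.56751,0.103905,0.0790768,1.7504918
145,1.53869,0.103761,0.078007,1.720458
146,1.5106,0.103617,0.0769586,1.6911756
147,1.4832,0.103473,0.0759311,1.6626041
148,1.45648,0.103328,0.074924,1.634732
149,1.43042,0.103184,0.0739367,1.6075407
150,1.40499,0.103039,0.0729687,1.5809977
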