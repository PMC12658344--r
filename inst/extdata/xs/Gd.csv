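# symbol=Gd Z=64 atomic_mass=157.2500 k_edge_keV=50.239
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,38859,0.00060672,10.3378,38869.33840672
2,6409.34,0.00208521,10.0555,6419.39758521
3,2233.45,0.00425075,9.61594,2243.07019075
4,1057.15,0.00698217,9.05821,1066.21519217
5,591.793,0.0101751,8.42563,600.2288051
6,368.382,0.0137347,7.75893,376.1546647
7,246.738,0.0175745,7.0918,253.8473745
7.243,225.789,0.0185408,6.93261,232.7401508
7.243,451.579,0.0185408,6.93261,458.5301508
7.93,354.533,0.0213279,6.49285,361.0471779
7.93,496.346,0.0213279,6.49285,502.8601779
8,484.835,0.0216159,6.44903,491.3056459
8.376,428.88,0.0231731,6.2172,435.1203731
8.376,428.88,0.0231731,6.2172,435.1203731
9,354.011,0.0257892,5.8467,359.8834892
10,267.205,0.0300332,5.29355,272.5285832
11,207.169,0.0342954,4.79277,211.9960654
12,164.221,0.0385316,4.34384,168.6033716
13,132.622,0.0427055,3.9439,136.6086055
14,108.813,0.0467876,3.58888,112.4486676
15,90.5066,0.0507552,3.27424,93.8315952
16,76.1805,0.0545907,2.99541,79.2305007
17,64.7956,0.0582817,2.74806,67.6019417
18,55.6245,0.0618196,2.52824,58.2145596
19,48.1473,0.0651993,2.33245,50.5449493
20,41.985,0.0684186,2.15759,44.2110086
21,36.8569,0.0714773,2.00098,38.9293573
22,32.5518,0.0743772,1.8603,34.4864772
23,28.9088,0.0771213,1.73356,30.7194813
24,25.8036,0.0797139,1.61904,27.5023539
25,23.139,0.0821599,1.51526,24.7364199
26,20.8384,0.0844647,1.42095,22.3438147
27,18.8409,0.0866341,1.33502,20.2625541
28,17.0975,0.0886743,1.25652,18.4426943
29,15.5683,0.0905912,1.18462,16.8435112
30,14.221,0.092391,1.11863,15.432021
31,13.0289,0.0940797,1.05791,14.1808897
32,11.97,0.0956632,1.00192,13.0675832
33,11.0258,0.0971472,0.950196,12.0731432
34,10.1811,0.0985373,0.902312,11.1819493
35,9.42285,0.0998386,0.857902,10.3805906
36,8.7401,0.101056,0.816641,9.657797
37,8.12354,0.102195,0.77824,9.003975
38,7.56522,0.10326,0.742444,8.410924
39,7.05832,0.104254,0.709024,7.871598
40,6.59696,0.105183,0.677775,7.379918
41,6.17605,0.106049,0.648516,6.930615
42,5.7912,0.106858,0.621083,6.519141
43,5.43855,0.107611,0.595327,6.141488
44,5.11476,0.108312,0.571117,5.794189
45,4.81689,0.108965,0.548332,5.474187
46,4.54235,0.109572,0.526863,5.178785
47,4.28887,0.110136,0.506613,4.905619
48,4.05443,0.110659,0.48749,4.652579
49,3.83725,0.111144,0.469415,4.417809
50,3.63575,0.111593,0.452312,4.199655
50.239,3.58975,0.111695,0.44836,4.149805
50.239,17.8411,0.111695,0.44836,18.401155
51,17.1262,0.112007,0.436113,17.67432
52,16.2451,0.11239,0.420757,16.778247
53,15.4249,0.112742,0.406187,15.943829
54,14.6602,0.113066,0.39235,15.165616
55,13.9465,0.113363,0.379199,14.439062
56,13.2795,0.113634,0.366689,13.759823
57,12.6553,0.113882,0.35478,13.123962
58,12.0706,0.114107,0.343434,12.528141
59,11.5222,0.114311,0.332617,11.969128
60,11.0073,0.114494,0.322297,11.444091
61,10.5234,0.114658,0.312443,10.950501
62,10.0681,0.114805,0.303029,10.485934
63,9.63931,0.114934,0.294029,10.048273
64,9.23513,0.115047,0.285419,9.635596
65,8.85377,0.115145,0.277177,9.246092
66,8.49362,0.115229,0.269283,8.878132
67,8.15321,0.115298,0.261718,8.530226
68,7.8312,0.115355,0.254463,8.201018
69,7.52632,0.1154,0.247502,7.889222
70,7.23745,0.115433,0.240821,7.593704
71,6.96353,0.115456,0.234403,7.313389
72,6.7036,0.115467,0.228235,7.047302
73,6.45675,0.11547,0.222305,6.794525
74,6.22217,0.115462,0.216601,6.554233
75,5.99909,0.115446,0.211112,6.325648
76,5.78681,0.115422,0.205826,6.108058
77,5.58467,0.115389,0.200735,5.900794
78,5.39206,0.11535,0.195828,5.703238
79,5.20843,0.115303,0.191097,5.51483
80,5.03324,0.115249,0.186534,5.335023
81,4.86601,0.115189,0.182131,5.16333
82,4.70629,0.115123,0.177881,4.999294
83,4.55365,0.115051,0.173776,4.842477
84,4.40771,0.114973,0.169811,4.692494
85,4.26808,0.114891,0.165979,4.54895
86,4.13444,0.114803,0.162273,4.411516
87,4.00645,0.114711,0.15869,4.279851
88,3.88382,0.114615,0.155222,4.153657
89,3.76627,0.114514,0.151867,4.032651
90,3.65353,0.11441,0.148618,3.916558
91,3.54536,0.114302,0.145471,3.805133
92,3.44151,0.11419,0.142423,3.698123
93,3.34179,0.114075,0.139468,3.595333
94,3.24597,0.113957,0.136604,3.496531
95,3.15387,0.113835,0.133826,3.401531
96,3.06531,0.113711,0.131132,3.310153
97,2.98012,0.113584,0.128518,3.222222
98,2.89813,0.113455,0.12598,3.137565
99,2.81919,0.113323,0.123517,3.05603
100,2.74317,0.113189,0.121124,2.977483
101,2.66992,0.113053,0.1188,2.901773
102,2.59932,0.112915,0.116541,2.828776
103,2.53125,0.112775,0.114346,2.758371
104,2.46559,0.112633,0.112212,2.690435
105,2.40225,0.112489,0.110137,2.624876
106,2.3411,0.112344,0.108119,2.561563
107,2.28207,0.112198,0.106155,2.500423
108,2.22505,0.11205,0.104243,2.441343
109,2.16996,0.1119,0.102383,2.384243
110,2.11672,0.11175,0.100572,2.329042
111,2.06526,0.111598,0.0988077,2.2756657
112,2.01548,0.111445,0.0970894,2.2240144
113,1.96734,0.111291,0.0954154,2.1740464
114,1.92075,0.111136,0.0937839,2.1256699
115,1.87566,0.110981,0.0921938,2.0788348
116,1.832,0.110824,0.0906435,2.0334675
117,1.78973,0.110667,0.0891318,1.9895288
118,1.74877,0.110509,0.0876573,1.9469363
119,1.70909,0.11035,0.086219,1.905659
120,1.67063,0.110191,0.0848155,1.8656365
121,1.63334,0.110032,0.0834459,1.8268179
122,1.59718,0.109871,0.082109,1.78916
123,1.56211,0.109711,0.0808039,1.7526249
124,1.52808,0.10955,0.0795294,1.7171594
125,1.49505,0.109388,0.0782847,1.6827227
126,1.463,0.109227,0.0770688,1.6492958
127,1.43188,0.109065,0.075881,1.616826
128,1.40166,0.108902,0.0747202,1.5852822
129,1.3723,0.10874,0.0735857,1.5546257
130,1.34377,0.108577,0.0724768,1.5248238
131,1.31606,0.108414,0.0713926,1.4958666
132,1.28911,0.108252,0.0703325,1.4676945
133,1.26292,0.108088,0.0692956,1.4403036
134,1.23745,0.107925,0.0682815,1.4136565
135,1.21268,0.107762,0.0672893,1.3877313
136,1.18857,0.107599,0.0663186,1.3624876
137,1.16512,0.107436,0.0653685,1.3379245
138,1.1423,0.107273,0.0644387,1.3140117
139,1.12009,0.10711,0.0635285,1.2907285
140,1.09846,0.106947,0.0626373,1.2680443
141,1.0774,0.106784,0.0617647,1.2459487
142,1.05689,0.106621,0.0609101,1.2244211
143,1.0369,0.106459,0.0600731,1.2034321
144,1.01743,0.106296,0.0592531,1.1829791
145,0.998462,0.106134,0.0584498,1.1630458
146,0.97997,0.105972,0.0576626,1.1436046
147,0.961943,0.10581,0.0568911,1.1246441
148,0.944366,0.105649,0.056135,1.10615
149,0.927226,0.105487,0.0553937,1.0881067
150,0.910509,0.105326,0.054667,1.070502
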