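# symbol=Bi Z=83 atomic_mass=208.9800 k_edge_keV=90.526
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,83908.1,0.000346217,13.1131,83921.213446217
2,13839.7,0.00119446,12.8404,13852.54159446
3,4822.68,0.00244875,12.4089,4835.09134875
4,2282.7,0.00405142,11.8488,2294.55285142
5,1277.86,0.00595493,11.1953,1289.06125493
6,795.446,0.00811653,10.4844,805.93851653
7,532.782,0.0104967,9.74864,542.5411367
8,376.504,0.0130584,9.01491,385.5319684
9,277.187,0.0157674,8.30371,285.5064774
10,210.768,0.0185917,7.62912,218.4157117
11,164.507,0.0215019,6.99972,171.5282219
12,131.2,0.0244715,6.41965,137.6441215
13,106.549,0.0274764,5.88983,112.4663064
13.419,98.1142,0.0287407,5.68252,103.8254607
13.419,196.228,0.0287407,5.68252,201.9392607
14,175.232,0.0304952,5.40897,180.6714652
15,145.751,0.033509,4.97436,150.758869
15.711,128.798,0.0356397,4.6916,133.5252397
15.711,180.318,0.0356397,4.6916,185.0452397
16,171.752,0.0365015,4.58255,176.3710515
16.388,161.108,0.0376537,4.44124,165.5868937
16.388,161.108,0.0376537,4.44124,165.5868937
17,146.084,0.0394584,4.22975,150.3532084
18,125.408,0.0423677,3.91215,129.3625177
19,108.55,0.0452195,3.62607,112.2212895
20,94.6569,0.0480054,3.36809,98.0729954
21,83.0954,0.050719,3.1351,86.281219
22,73.3895,0.0533549,2.92427,76.3671249
23,65.1762,0.0559093,2.73313,67.9652393
24,58.1753,0.0583794,2.55945,60.7931294
25,52.1678,0.0607634,2.40129,54.6298534
26,46.9812,0.0630603,2.25694,49.3012003
27,42.4777,0.0652699,2.12489,44.6678599
28,38.547,0.0673925,2.00384,40.6182325
29,35.0994,0.069429,1.89263,37.061459
30,32.0619,0.0713806,1.79025,33.9235306
31,29.3743,0.0732488,1.6958,31.1433488
32,26.9868,0.0750357,1.6085,28.6703357
33,24.8582,0.0767433,1.52765,26.4625933
34,22.9538,0.0783737,1.45265,24.4848237
35,21.2442,0.0799295,1.38294,22.7070695
36,19.7049,0.081413,1.31806,21.104373
37,18.3149,0.0828267,1.25756,19.6552867
38,17.0561,0.0841731,1.20107,18.3413431
39,15.9133,0.0854548,1.14824,17.1469948
40,14.8731,0.0866742,1.09877,16.0585442
41,13.9242,0.0878338,1.05237,15.0644038
42,13.0565,0.0889361,1.00881,14.1542461
43,12.2614,0.0899834,0.967856,13.3192394
44,11.5314,0.090978,0.929306,12.551684
45,10.8599,0.0919222,0.892978,11.8448002
46,10.2409,0.0928182,0.858706,11.1924242
47,9.66944,0.093668,0.826339,10.589447
48,9.14089,0.0944736,0.79574,10.0311036
49,8.65125,0.0952372,0.766783,9.5132702
50,8.19696,0.0959604,0.739354,9.0322744
51,7.77482,0.0966451,0.713349,8.5848141
52,7.38199,0.0972932,0.688671,8.1679542
53,7.01594,0.0979061,0.665233,7.7790791
54,6.67438,0.0984855,0.642953,7.4158185
55,6.35527,0.099033,0.621757,7.07606
56,6.05676,0.0995499,0.601578,6.7578879
57,5.77719,0.100038,0.58235,6.459578
58,5.51505,0.100498,0.564016,6.179564
59,5.26899,0.100931,0.546523,5.916444
60,5.03777,0.101339,0.529819,5.668928
61,4.82028,0.101723,0.513858,5.435861
62,4.61548,0.102084,0.498598,5.216162
63,4.42245,0.102422,0.483999,5.008871
64,4.24035,0.10274,0.470023,4.813113
65,4.0684,0.103038,0.456635,4.628073
66,3.90589,0.103316,0.443804,4.45301
67,3.75217,0.103576,0.431499,4.287245
68,3.60665,0.103819,0.419692,4.130161
69,3.46877,0.104045,0.408356,3.981171
70,3.33803,0.104254,0.397468,3.839752
71,3.21398,0.104449,0.387005,3.705434
72,3.09617,0.104629,0.376944,3.577743
73,2.98422,0.104795,0.367265,3.45628
74,2.87776,0.104948,0.35795,3.340658
75,2.77644,0.105088,0.348981,3.230509
76,2.67997,0.105216,0.340341,3.125527
77,2.58805,0.105332,0.332014,3.025396
78,2.5004,0.105437,0.323985,2.929822
79,2.41679,0.105531,0.316241,2.838562
80,2.33697,0.105616,0.308768,2.751354
81,2.26072,0.10569,0.301554,2.667964
82,2.18786,0.105756,0.294587,2.588203
83,2.11819,0.105812,0.287856,2.511858
84,2.05153,0.10586,0.281351,2.438741
85,1.98771,0.1059,0.275062,2.368672
86,1.9266,0.105932,0.268979,2.301511
87,1.86804,0.105956,0.263093,2.237089
88,1.8119,0.105973,0.257397,2.17527
89,1.75805,0.105984,0.251881,2.115915
90,1.70638,0.105988,0.24654,2.058908
90.526,1.68003,0.105987,0.243798,2.029815
90.526,7.26446,0.105987,0.243798,7.614245
91,7.162,0.105986,0.241365,7.509351
92,6.95223,0.105977,0.23635,7.294557
93,6.75077,0.105963,0.231487,7.08822
94,6.55721,0.105944,0.226772,6.889926
95,6.37116,0.105919,0.222199,6.699278
96,6.19226,0.10589,0.217761,6.515911
97,6.02016,0.105855,0.213453,6.339468
98,5.85453,0.105816,0.209271,6.169617
99,5.69507,0.105772,0.20521,6.006052
100,5.54149,0.105725,0.201264,5.848479
101,5.39353,0.105673,0.197431,5.696634
102,5.25091,0.105617,0.193705,5.550232
103,5.1134,0.105558,0.190082,5.40904
104,4.98077,0.105495,0.18656,5.272825
105,4.8528,0.105429,0.183133,5.141362
106,4.72928,0.105359,0.1798,5.014439
107,4.61002,0.105287,0.176556,4.891863
108,4.49484,0.105211,0.173398,4.773449
109,4.38356,0.105133,0.170323,4.659016
110,4.27601,0.105051,0.167329,4.54839
111,4.17204,0.104968,0.164413,4.441421
112,4.07149,0.104881,0.161572,4.337943
113,3.97423,0.104793,0.158803,4.237826
114,3.88012,0.104702,0.156104,4.140926
115,3.78904,0.104609,0.153473,4.047122
116,3.70085,0.104514,0.150908,3.956272
117,3.61544,0.104417,0.148405,3.868262
118,3.53271,0.104318,0.145965,3.782993
119,3.45254,0.104217,0.143583,3.70034
120,3.37485,0.104115,0.141259,3.620224
121,3.29952,0.104011,0.13899,3.542521
122,3.22647,0.103905,0.136776,3.467151
123,3.15562,0.103798,0.134613,3.394031
124,3.08688,0.103689,0.132501,3.32307
125,3.02017,0.103579,0.130438,3.254187
126,2.95542,0.103468,0.128423,3.187311
127,2.89255,0.103355,0.126453,3.122358
128,2.83149,0.103242,0.124529,3.059261
129,2.77219,0.103127,0.122647,2.997964
130,2.71457,0.103011,0.120808,2.938389
131,2.65858,0.102894,0.11901,2.880484
132,2.60415,0.102776,0.117251,2.824177
133,2.55123,0.102658,0.115531,2.769419
134,2.49978,0.102538,0.113848,2.716166
135,2.44973,0.102418,0.112201,2.664349
136,2.40105,0.102297,0.11059,2.613937
137,2.35368,0.102175,0.109012,2.564867
138,2.30757,0.102052,0.107469,2.517091
139,2.2627,0.101929,0.105957,2.470586
140,2.21901,0.101805,0.104477,2.425292
141,2.17646,0.101681,0.103028,2.381169
142,2.13502,0.101556,0.101608,2.338184
143,2.09466,0.101431,0.100218,2.296309
144,2.05533,0.101305,0.0988556,2.2554906
145,2.017,0.101178,0.0975208,2.2156988
146,1.97964,0.101052,0.0962126,2.1769046
147,1.94323,0.100925,0.0949305,2.1390855
148,1.90772,0.100797,0.0936737,2.1021907
149,1.8731,0.100669,0.0924416,2.0662106
150,1.83933,0.100541,0.0912336,2.0311046
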