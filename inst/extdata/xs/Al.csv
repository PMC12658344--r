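# symbol=Al Z=13 atomic_mass=26.9820 k_edge_keV=NA
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,35168.6,0.0177336,2.38332,35171.0010536
2,3998.61,0.0500536,2.06833,4000.7283836
3,1120.88,0.0807642,1.69035,1122.6511142
4,454.634,0.104908,1.34324,456.082148
5,225.778,0.122693,1.0626,226.963293
6,127.442,0.135581,0.847954,128.425535
7,78.5814,0.144948,0.686447,79.412795
8,51.691,0.151824,0.564479,52.407303
9,35.7243,0.156928,0.471187,36.352415
10,25.6706,0.160756,0.398676,26.230032
11,19.2734,0.163648,0.341388,19.778436
12,14.836,0.165845,0.295422,15.297267
13,11.6622,0.167514,0.258018,12.087732
14,9.33236,0.16878,0.227195,9.728335
15,7.58376,0.169731,0.201508,7.954999
16,6.20472,0.170435,0.179883,6.555038
17,5.13861,0.170941,0.161514,5.471065
18,4.3018,0.171289,0.145782,4.618871
19,3.63605,0.171507,0.132211,3.939768
20,3.09995,0.17162,0.120425,3.391995
21,2.67197,0.171646,0.110127,2.953743
22,2.31905,0.1716,0.101078,2.591728
23,2.02546,0.171494,0.0930857,2.2900397
24,1.77926,0.171337,0.0859937,2.0365907
25,1.57128,0.171137,0.0796726,1.8220896
26,1.39439,0.170902,0.0740156,1.6393076
27,1.24301,0.170636,0.0689334,1.4825794
28,1.1127,0.170344,0.0643516,1.3473956
29,0.999934,0.170031,0.0602069,1.2301719
30,0.901856,0.169698,0.056446,1.128
31,0.814835,0.169349,0.0530233,1.0372073
32,0.738587,0.168987,0.0498997,0.9574737
33,0.671501,0.168613,0.0470417,0.8871557
34,0.612247,0.168229,0.0444201,0.8248961
35,0.559718,0.167836,0.0420098,0.7695638
36,0.512991,0.167437,0.0397888,0.7202168
37,0.471289,0.167031,0.037738,0.676058
38,0.433957,0.16662,0.0358405,0.6364175
39,0.40044,0.166206,0.0340816,0.6007276
40,0.370265,0.165787,0.032448,0.5685
41,0.343018,0.165366,0.0309283,0.5393123
42,0.318361,0.164943,0.0295122,0.5128162
43,0.295996,0.164518,0.0281905,0.4887045
44,0.275664,0.164092,0.0269551,0.4667111
45,0.257139,0.163665,0.0257986,0.4466026
46,0.240226,0.163238,0.0247146,0.4281786
47,0.224754,0.16281,0.0236971,0.4112611
48,0.210574,0.162383,0.0227407,0.3956977
49,0.197553,0.161956,0.0218408,0.3813498
50,0.185577,0.16153,0.020993,0.3681
51,0.174589,0.161104,0.0201934,0.3558864
52,0.164446,0.16068,0.0194384,0.3445644
53,0.15507,0.160256,0.0187247,0.3340507
54,0.146388,0.159834,0.0180494,0.3242714
55,0.138339,0.159414,0.0174099,0.3151629
56,0.130865,0.158995,0.0168036,0.3066636
57,0.123917,0.158577,0.0162282,0.2987222
58,0.11745,0.158161,0.0156818,0.2912928
59,0.111421,0.157747,0.0151625,0.2843305
60,0.105796,0.157335,0.0146684,0.2777994
61,0.10059,0.156925,0.014198,0.271713
62,0.0957188,0.156517,0.0137497,0.2659855
63,0.0911557,0.15611,0.0133223,0.260588
64,0.0868769,0.155706,0.0129144,0.2554973
65,0.0828606,0.155304,0.0125249,0.2506895
66,0.0790872,0.154904,0.0121527,0.2461439
67,0.0755385,0.154506,0.0117968,0.2418413
68,0.0721982,0.154111,0.0114563,0.2377655
69,0.0690511,0.153717,0.0111302,0.2338983
70,0.0660836,0.153326,0.0108179,0.2302275
71,0.0632831,0.152937,0.0105184,0.2267385
72,0.0606379,0.15255,0.0102312,0.2234191
73,0.0581375,0.152166,0.00995554,0.22025904
74,0.0557722,0.151784,0.00969085,0.21724705
75,0.053533,0.151404,0.00943655,0.21437355
76,0.0514115,0.151026,0.0091921,0.2116296
77,0.0494002,0.15065,0.008957,0.2090072
78,0.0474921,0.150277,0.00873078,0.20649988
79,0.0456806,0.149906,0.00851301,0.20409961
80,0.0439597,0.149537,0.00830326,0.20179996
81,0.0423458,0.149171,0.00810115,0.19961795
82,0.0408099,0.148806,0.00790631,0.19752221
83,0.0393473,0.148444,0.0077184,0.1955097
84,0.0379537,0.148084,0.0075371,0.1935748
85,0.0366251,0.147726,0.00736209,0.19171319
86,0.0353578,0.147371,0.0071931,0.1899219
87,0.0341482,0.147018,0.00702985,0.18819605
88,0.0329931,0.146666,0.00687208,0.18653118
89,0.0318894,0.146317,0.00671955,0.18492595
90,0.0308345,0.145971,0.00657203,0.18337753
91,0.0298255,0.145626,0.00642931,0.18188081
92,0.02886,0.145283,0.00629118,0.18043418
93,0.0279357,0.144943,0.00615744,0.17903614
94,0.0270504,0.144605,0.00602792,0.17768332
95,0.0262021,0.144268,0.00590243,0.17637253
96,0.0253889,0.143934,0.00578081,0.17510371
97,0.0246089,0.143602,0.00566291,0.17387381
98,0.0238606,0.143272,0.00554857,0.17268117
99,0.0231422,0.142944,0.00543765,0.17152385
100,0.0224524,0.142618,0.00533002,0.17040042
101,0.021809,0.142294,0.00522555,0.16932855
102,0.02119,0.141971,0.00512412,0.16828512
103,0.0205945,0.141651,0.0050256,0.1672711
104,0.0200211,0.141333,0.0049299,0.166284
105,0.019469,0.141017,0.0048369,0.1653229
106,0.0189372,0.140703,0.0047465,0.1643867
107,0.0184246,0.14039,0.0046586,0.1634732
108,0.0179305,0.14008,0.00457313,0.16258363
109,0.0174541,0.139771,0.00448998,0.16171508
110,0.0169944,0.139464,0.00440907,0.16086747
111,0.0165509,0.139159,0.00433033,0.16004023
112,0.0161228,0.138856,0.00425368,0.15923248
113,0.0157094,0.138555,0.00417904,0.15844344
114,0.0153101,0.138255,0.00410635,0.15767145
115,0.0149243,0.137958,0.00403553,0.15691783
116,0.0145514,0.137662,0.00396653,0.15617993
117,0.014191,0.137368,0.00389928,0.15545828
118,0.0138424,0.137075,0.00383372,0.15475112
119,0.0135052,0.136785,0.0037698,0.15406
120,0.013179,0.136496,0.00370746,0.15338246
121,0.0128633,0.136209,0.00364666,0.15271896
122,0.0125576,0.135923,0.00358734,0.15206794
123,0.0122616,0.135639,0.00352945,0.15143005
124,0.0119748,0.135357,0.00347295,0.15080475
125,0.011697,0.135076,0.00341779,0.15019079
126,0.0114278,0.134797,0.00336394,0.14958874
127,0.0111669,0.13452,0.00331134,0.14899824
128,0.0109139,0.134244,0.00325997,0.14841787
129,0.0106685,0.13397,0.00320979,0.14784829
130,0.0104304,0.133698,0.00316075,0.14728915
131,0.0101995,0.133427,0.00311283,0.14673933
132,0.00997532,0.133157,0.00306599,0.14619831
133,0.00975773,0.132889,0.00302019,0.14566692
134,0.00954646,0.132623,0.00297541,0.14514487
135,0.00934129,0.132358,0.00293162,0.14463091
136,0.00914199,0.132095,0.00288879,0.14412578
137,0.00894836,0.131833,0.00284689,0.14362825
138,0.0087602,0.131572,0.0028059,0.1431381
139,0.00857731,0.131313,0.00276578,0.14265609
140,0.0083995,0.131056,0.00272651,0.14218201
141,0.00822661,0.1308,0.00268808,0.14171469
142,0.00805846,0.130545,0.00265045,0.14125391
143,0.00789489,0.130292,0.00261361,0.1408005
144,0.00773575,0.13004,0.00257752,0.14035327
145,0.00758089,0.12979,0.00254218,0.13991307
146,0.00743015,0.129541,0.00250756,0.13947871
147,0.00728341,0.129293,0.00247364,0.13905005
148,0.00714054,0.129047,0.00244041,0.13862795
149,0.0070014,0.128802,0.00240784,0.13821124
150,0.00686588,0.128558,0.00237591,0.13779979
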