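# symbol=Ba Z=56 atomic_mass=137.3270 k_edge_keV=37.441
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,26918.5,0.000800494,9.05005,26927.550850494
2,4439.9,0.0027432,8.76607,4448.6688132
3,1547.16,0.00556827,8.32829,1555.49385827
4,732.311,0.00909713,7.78063,740.10072713
5,409.949,0.0131739,7.16999,417.1321639
5.247,361.645,0.0142488,7.0145,368.6737488
5.247,723.29,0.0142488,7.0145,730.3187488
5.624,600.972,0.0159327,6.77604,607.7639727
5.624,841.361,0.0159327,6.77604,848.1529727
5.989,711.324,0.0176072,6.54536,717.8869672
5.989,711.324,0.0176072,6.54536,717.8869672
6,707.847,0.0176583,6.53843,714.4030883
7,469.02,0.0224245,5.91871,474.9611345
8,328.362,0.0273627,5.33312,333.7224827
9,239.759,0.0323788,4.79446,244.5858388
10,180.969,0.0373944,4.30824,185.3146344
11,140.309,0.0423461,3.87489,144.2262361
12,111.222,0.0471838,3.49176,114.7609438
13,89.8203,0.0518696,3.15458,93.0267496
14,73.6956,0.0563758,2.85842,76.6103958
15,61.297,0.0606837,2.59831,63.9559937
16,51.5944,0.0647815,2.36958,54.0287615
17,43.8838,0.0686631,2.16802,46.1204831
18,37.6726,0.0723272,1.98989,39.7348172
19,32.6085,0.0757759,1.83198,34.5162559
20,28.435,0.0790139,1.69153,30.2055439
21,24.9619,0.0820477,1.56618,26.6101277
22,22.0462,0.0848854,1.45392,23.5850054
23,19.579,0.0875357,1.35304,21.0195757
24,17.4759,0.0900079,1.26211,18.8280179
25,15.6712,0.0923117,1.17987,16.9433817
26,14.1132,0.0944564,1.10528,15.3129364
27,12.7603,0.0964516,1.03742,13.8941716
28,11.5795,0.0983064,0.97553,12.6533364
29,10.5439,0.10003,0.918925,11.562855
30,9.6314,0.10163,0.867031,10.600061
31,8.82404,0.103114,0.819343,9.746497
32,8.10686,0.104492,0.775423,8.986775
33,7.46743,0.105768,0.734887,8.308085
34,6.89532,0.106951,0.697399,7.69967
35,6.38178,0.108047,0.662665,7.152492
36,5.91937,0.109061,0.630422,6.658853
37,5.5018,0.109998,0.60044,6.212238
37.441,5.33047,0.110389,0.587883,6.028742
37.441,27.9423,0.110389,0.587883,28.640572
38,26.8384,0.110865,0.572515,27.52178
39,25.0076,0.111665,0.546464,25.665729
40,23.3434,0.112404,0.522124,23.977928
41,21.8271,0.113084,0.499351,22.439535
42,20.4423,0.113711,0.478013,21.034024
43,19.1749,0.114287,0.457994,19.747181
44,18.0126,0.114817,0.439189,18.566606
45,16.9445,0.115302,0.421501,17.481303
46,15.9612,0.115746,0.404845,16.481791
47,15.0543,0.116152,0.389144,15.559596
48,14.2165,0.116521,0.374325,14.707346
49,13.4411,0.116857,0.360325,13.918282
50,12.7224,0.117161,0.347086,13.186647
51,12.0553,0.117436,0.334553,12.507289
52,11.4351,0.117683,0.322677,11.87546
53,10.8577,0.117904,0.311415,11.287019
54,10.3195,0.1181,0.300724,10.738324
55,9.81705,0.118274,0.290567,10.225891
56,9.34751,0.118426,0.28091,9.746846
57,8.90816,0.118558,0.271721,9.298439
58,8.49657,0.118671,0.262969,8.87821
59,8.11055,0.118766,0.254629,8.483945
60,7.74812,0.118845,0.246674,8.113639
61,7.40748,0.118908,0.239082,7.76547
62,7.087,0.118956,0.231831,7.437787
63,6.78518,0.118989,0.224901,7.12907
64,6.50067,0.11901,0.218274,6.837954
65,6.23223,0.119019,0.211933,6.563182
66,5.97872,0.119016,0.205861,6.303597
67,5.7391,0.119002,0.200043,6.058145
68,5.51243,0.118977,0.194466,5.825873
69,5.29783,0.118943,0.189116,5.605889
70,5.09449,0.1189,0.183982,5.397372
71,4.90168,0.118848,0.179052,5.19958
72,4.71871,0.118788,0.174316,5.011814
73,4.54495,0.118721,0.169763,4.833434
74,4.37983,0.118646,0.165385,4.663861
75,4.2228,0.118564,0.161172,4.502536
76,4.07338,0.118476,0.157117,4.348973
77,3.93109,0.118382,0.153212,4.202684
78,3.79551,0.118283,0.149449,4.063242
79,3.66625,0.118177,0.145822,3.930249
80,3.54293,0.118067,0.142324,3.803321
81,3.42522,0.117952,0.138949,3.682121
82,3.31279,0.117833,0.135692,3.566315
83,3.20535,0.117709,0.132547,3.455606
84,3.10262,0.117582,0.12951,3.349712
85,3.00433,0.11745,0.126575,3.248355
86,2.91026,0.117315,0.123737,3.151312
87,2.82017,0.117177,0.120994,3.058341
88,2.73385,0.117036,0.11834,2.969226
89,2.6511,0.116891,0.115771,2.883762
90,2.57175,0.116744,0.113285,2.801779
91,2.4956,0.116595,0.110877,2.723072
92,2.42251,0.116443,0.108545,2.647498
93,2.35231,0.116288,0.106285,2.574883
94,2.28486,0.116132,0.104095,2.505087
95,2.22003,0.115973,0.101971,2.437974
96,2.15769,0.115813,0.0999107,2.3734137
97,2.09772,0.115651,0.097912,2.311283
98,2.04001,0.115487,0.0959723,2.2514693
99,1.98445,0.115322,0.0940893,2.1938613
100,1.93093,0.115155,0.0922608,2.1383458
101,1.87937,0.114987,0.0904848,2.0848418
102,1.82968,0.114818,0.0887592,2.0332572
103,1.78176,0.114647,0.0870823,1.9834893
104,1.73555,0.114476,0.0854521,1.9354781
105,1.69096,0.114304,0.0838671,1.8891311
106,1.64792,0.11413,0.0823254,1.8443754
107,1.60636,0.113956,0.0808257,1.8011417
108,1.56623,0.113781,0.0793663,1.7593773
109,1.52745,0.113606,0.0779459,1.7190019
110,1.48998,0.11343,0.076563,1.679973
111,1.45375,0.113253,0.0752165,1.6422195
112,1.41871,0.113076,0.0739049,1.6056909
113,1.38482,0.112898,0.0726272,1.5703452
114,1.35203,0.11272,0.0713822,1.5361322
115,1.32029,0.112542,0.0701687,1.5030007
116,1.28956,0.112363,0.0689858,1.4709088
117,1.2598,0.112184,0.0678324,1.4398164
118,1.23097,0.112005,0.0667075,1.4096825
119,1.20304,0.111826,0.0656102,1.3804762
120,1.17597,0.111646,0.0645397,1.3521557
121,1.14972,0.111467,0.063495,1.324682
122,1.12427,0.111287,0.0624754,1.2980324
123,1.09958,0.111108,0.06148,1.272168
124,1.07562,0.110928,0.0605081,1.2470561
125,1.05238,0.110748,0.059559,1.222687
126,1.02982,0.110569,0.0586319,1.1990209
127,1.00791,0.110389,0.0577262,1.1760252
128,0.986635,0.11021,0.0568413,1.1536863
129,0.96597,0.110031,0.0559764,1.1319774
130,0.945892,0.109852,0.0551311,1.1108751
131,0.926381,0.109673,0.0543047,1.0903587
132,0.907416,0.109495,0.0534966,1.0704076
133,0.888978,0.109316,0.0527064,1.0510004
134,0.871049,0.109138,0.0519335,1.0321205
135,0.85361,0.10896,0.0511774,1.0137474
136,0.836646,0.108783,0.0504377,0.9958667
137,0.820139,0.108605,0.0497137,0.9784577
138,0.804075,0.108428,0.0490053,0.9615083
139,0.788438,0.108252,0.0483117,0.9450017
140,0.773213,0.108075,0.0476328,0.9289208
141,0.758388,0.107899,0.046968,0.913255
142,0.743949,0.107724,0.046317,0.89799
143,0.729884,0.107549,0.0456794,0.8831124
144,0.716179,0.107374,0.0450548,0.8686078
145,0.702824,0.107199,0.0444428,0.8544658
146,0.689807,0.107025,0.0438433,0.8406753
147,0.677118,0.106852,0.0432557,0.8272257
148,0.664746,0.106679,0.0426798,0.8141048
149,0.652681,0.106506,0.0421153,0.8013023
150,0.640913,0.106334,0.0415619,0.7888089
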