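# symbol=H Z=1 atomic_mass=1.0080 k_edge_keV=NA
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,19.194,0.377521,0.213,19.784521
2,2.18232,0.388926,0.089572,2.660818
3,0.611745,0.390216,0.0468878,1.0488488
4,0.248126,0.389779,0.0285532,0.6664582
5,0.123223,0.388812,0.0191167,0.5311517
6,0.0695542,0.387634,0.0136516,0.4708398
7,0.0428874,0.38636,0.0102162,0.4394636
8,0.0282115,0.38504,0.00792211,0.42117361
9,0.0194973,0.383697,0.00631702,0.40951132
10,0.0140103,0.382344,0.00515163,0.40150593
11,0.00985498,0.38099,0.0042796,0.39512458
12,0.00714775,0.379638,0.00361052,0.39039627
13,0.0053193,0.378293,0.00308623,0.38669853
14,0.00404626,0.376954,0.00266792,0.38366818
15,0.00313655,0.375624,0.00232892,0.38108947
16,0.00253078,0.374304,0.00205045,0.37888523
17,0.00206876,0.372993,0.00181895,0.37688071
18,0.00171068,0.371693,0.00162444,0.37502812
19,0.0014292,0.370404,0.00145946,0.37329266
20,0.0012051,0.369125,0.00131834,0.37164844
21,0.00101373,0.367857,0.0011967,0.37006743
22,0.000859632,0.3666,0.00109111,0.368550742
23,0.000734324,0.365353,0.00099888,0.367086204
24,0.000631503,0.364118,0.000917848,0.365667351
25,0.000546435,0.362893,0.000846275,0.36428571
26,0.000475517,0.361678,0.000782746,0.362936263
27,0.00041598,0.360475,0.0007261,0.36161708
28,0.000365672,0.359281,0.00067538,0.360322052
29,0.000322905,0.358098,0.000629788,0.359050693
30,0.000286346,0.356925,0.000588655,0.357800001
31,0.000257994,0.355763,0.00055142,0.356572414
32,0.00023322,0.35461,0.000517605,0.355360825
33,0.000211481,0.353467,0.000486805,0.354165286
34,0.000192329,0.352334,0.000458671,0.352985
35,0.000175394,0.351211,0.000432905,0.351819299
36,0.000160365,0.350097,0.000409249,0.350666614
37,0.000146985,0.348993,0.000387479,0.349527464
38,0.000135035,0.347898,0.000367399,0.348400434
39,0.00012433,0.346813,0.000348839,0.347286169
40,0.000114713,0.345736,0.000331649,0.346182362
41,0.000106689,0.344669,0.000315699,0.345091388
42,9.94001e-05,0.34361,0.000300871,0.3440102711
43,9.27635e-05,0.34256,0.000287063,0.3429398265
44,8.67076e-05,0.341519,0.000274183,0.3418798906
45,8.11701e-05,0.340487,0.000262151,0.3408303211
46,7.60966e-05,0.339463,0.000250893,0.3397899896
47,7.14393e-05,0.338447,0.000240344,0.3387587833
48,6.71563e-05,0.33744,0.000230447,0.3377376033
49,6.32106e-05,0.33644,0.000221148,0.3367243586
50,5.95695e-05,0.335449,0.0002124,0.3357209695
51,5.68124e-05,0.334466,0.000204161,0.3347269734
52,5.42327e-05,0.333491,0.000196392,0.3337416247
53,5.18161e-05,0.332524,0.000189058,0.3327648741
54,4.95493e-05,0.331564,0.000182126,0.3317956753
55,4.74206e-05,0.330612,0.000175569,0.3308349896
56,4.54192e-05,0.329667,0.00016936,0.3298817792
57,4.35356e-05,0.32873,0.000163474,0.3289370096
58,4.17608e-05,0.3278,0.000157889,0.3279996498
59,4.00869e-05,0.326878,0.000152585,0.3270706719
60,3.85065e-05,0.325962,0.000147544,0.3261480505
61,3.69864e-05,0.325054,0.000142749,0.3252337354
62,3.55495e-05,0.324153,0.000138184,0.3243267335
63,3.41902e-05,0.323258,0.000133833,0.3234260232
64,3.2903e-05,0.322371,0.000129685,0.322533588
65,3.16831e-05,0.32149,0.000125727,0.3216474101
66,3.05261e-05,0.320616,0.000121947,0.3207684731
67,2.94277e-05,0.319748,0.000118335,0.3198957627
68,2.83843e-05,0.318887,0.000114881,0.3190302653
69,2.73923e-05,0.318033,0.000111576,0.3181719683
70,2.64485e-05,0.317185,0.000108411,0.3173198595
71,2.555e-05,0.316343,0.00010538,0.31647393
72,2.46939e-05,0.315507,0.000102473,0.3156341669
73,2.38777e-05,0.314678,9.96848e-05,0.3148015625
74,2.3099e-05,0.313854,9.70088e-05,0.3139741078
75,2.23557e-05,0.313037,9.44391e-05,0.3131537948
76,2.16457e-05,0.312226,9.19701e-05,0.3123396158
77,2.09671e-05,0.31142,8.95966e-05,0.3115305637
78,2.03181e-05,0.310621,8.73137e-05,0.3107286318
79,1.96971e-05,0.309827,8.51169e-05,0.309931814
80,1.91025e-05,0.309039,8.30019e-05,0.3091411044
81,1.85612e-05,0.308256,8.09646e-05,0.3083555258
82,1.80417e-05,0.307479,7.90015e-05,0.3075760432
83,1.75427e-05,0.306708,7.71087e-05,0.3068026514
84,1.70632e-05,0.305942,7.52832e-05,0.3060343464
85,1.66023e-05,0.305181,7.35216e-05,0.3052711239
86,1.6159e-05,0.304426,7.18211e-05,0.3045139801
87,1.57325e-05,0.303676,7.01789e-05,0.3037619114
88,1.53219e-05,0.302931,6.85923e-05,0.3030149142
89,1.49265e-05,0.302191,6.70588e-05,0.3022729853
90,1.45455e-05,0.301457,6.55761e-05,0.3015371216
91,1.41784e-05,0.300728,6.41421e-05,0.3008063205
92,1.38243e-05,0.300003,6.27545e-05,0.3000795788
93,1.34828e-05,0.299284,6.14114e-05,0.2993588942
94,1.31532e-05,0.298569,6.01109e-05,0.2986422641
95,1.28351e-05,0.297859,5.88512e-05,0.2979306863
96,1.25278e-05,0.297154,5.76307e-05,0.2972241585
97,1.2231e-05,0.296454,5.64477e-05,0.2965226787
98,1.19442e-05,0.295759,5.53008e-05,0.295826245
99,1.16668e-05,0.295068,5.41884e-05,0.2951338552
100,1.13987e-05,0.294381,5.31091e-05,0.2944455078
101,1.12552e-05,0.2937,5.20618e-05,0.293763317
102,1.11148e-05,0.293022,5.10451e-05,0.2930841599
103,1.09776e-05,0.29235,5.00579e-05,0.2924110355
104,1.08434e-05,0.291681,4.9099e-05,0.2917409424
105,1.07121e-05,0.291017,4.81673e-05,0.2910758794
106,1.05836e-05,0.290358,4.72619e-05,0.2904158455
107,1.04578e-05,0.289702,4.63817e-05,0.2897588395
108,1.03347e-05,0.289051,4.55259e-05,0.2891068606
109,1.02141e-05,0.288404,4.46935e-05,0.2884589076
110,1.0096e-05,0.287761,4.38836e-05,0.2878149796
111,9.98037e-06,0.287122,4.30956e-05,0.28717507597
112,9.86705e-06,0.286488,4.23286e-05,0.28654019565
113,9.75601e-06,0.285857,4.15818e-05,0.28590833781
114,9.64717e-06,0.28523,4.08546e-05,0.28528050177
115,9.54049e-06,0.284608,4.01463e-05,0.28465768679
116,9.4359e-06,0.283989,3.94562e-05,0.2840378921
117,9.33333e-06,0.283374,3.87837e-05,0.28342211703
118,9.23274e-06,0.282763,3.81282e-05,0.28281036094
119,9.13407e-06,0.282155,3.74892e-05,0.28220162327
120,9.03726e-06,0.281552,3.68661e-05,0.28159790336
121,8.94228e-06,0.280952,3.62584e-05,0.28099720068
122,8.84906e-06,0.280356,3.56655e-05,0.28040051456
123,8.75756e-06,0.279763,3.50871e-05,0.27980684466
124,8.66773e-06,0.279174,3.45226e-05,0.27921719033
125,8.57954e-06,0.278589,3.39715e-05,0.27863155104
126,8.49294e-06,0.278007,3.34336e-05,0.27804892654
127,8.40788e-06,0.277429,3.29083e-05,0.27747031618
128,8.32434e-06,0.276854,3.23952e-05,0.27689471954
129,8.24226e-06,0.276282,3.1894e-05,0.27632213626
130,8.16162e-06,0.275714,3.14044e-05,0.27575356602
131,8.08238e-06,0.27515,3.09259e-05,0.27518900828
132,8.0045e-06,0.274589,3.04582e-05,0.2746274627
133,7.92795e-06,0.274031,3.00011e-05,0.27406892905
134,7.8527e-06,0.273476,2.95541e-05,0.2735134068
135,7.77871e-06,0.272925,2.91171e-05,0.27296189581
136,7.70596e-06,0.272376,2.86896e-05,0.27241239556
137,7.63441e-06,0.271831,2.82715e-05,0.27186690591
138,7.56405e-06,0.271289,2.78624e-05,0.27132442645
139,7.49483e-06,0.270751,2.74621e-05,0.27078595693
140,7.42673e-06,0.270215,2.70704e-05,0.27024949713
141,7.35973e-06,0.269683,2.66869e-05,0.26971704663
142,7.29381e-06,0.269153,2.63116e-05,0.26918660541
143,7.22892e-06,0.268627,2.5944e-05,0.26866017292
144,7.16507e-06,0.268103,2.55841e-05,0.26813574917
145,7.10221e-06,0.267583,2.52317e-05,0.26761533391
146,7.04033e-06,0.267065,2.48864e-05,0.26709692673
147,6.97941e-06,0.26655,2.45482e-05,0.26658152761
148,6.91942e-06,0.266039,2.42168e-05,0.26607013622
149,6.86035e-06,0.26553,2.3892e-05,0.26556075235
150,6.80217e-06,0.265024,2.35737e-05,0.26505437587
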