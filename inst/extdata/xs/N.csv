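# symbol=N Z=7 atomic_mass=14.0070 k_edge_keV=NA
# mass interaction coefficients, cm^2/g; approximate standard tabulation
# reconstruction, see data-raw/make_physics_tables.R
energy_keV,photoelectric,incoherent,coherent,total
1,4998.37,0.0534295,1.27011,4999.6935395
2,568.305,0.11131,0.987406,569.403716
3,159.306,0.143586,0.717281,160.166867
4,64.6152,0.160883,0.518967,65.29505
5,32.0889,0.170653,0.384592,32.644145
6,18.1128,0.176479,0.293772,18.583051
7,11.1684,0.180092,0.230812,11.579304
8,7.34662,0.182383,0.18576,7.714763
9,5.07734,0.183842,0.152535,5.413717
10,3.64845,0.184752,0.127374,3.960576
11,2.69648,0.185288,0.107885,2.989653
12,2.04606,0.18556,0.0924931,2.3241131
13,1.58724,0.185642,0.0801332,1.8530152
14,1.25471,0.185584,0.0700638,1.5103578
15,1.00807,0.18542,0.061756,1.255246
16,0.821996,0.185176,0.0548249,1.0619969
17,0.678618,0.18487,0.0489845,0.9124725
18,0.566422,0.184516,0.0440194,0.7949574
19,0.477419,0.184124,0.0397643,0.7013073
20,0.405945,0.183703,0.0360911,0.6257391
21,0.347849,0.183257,0.0328991,0.5640051
22,0.300216,0.182793,0.0301085,0.5131175
23,0.260809,0.182315,0.0276552,0.4707792
24,0.227935,0.181824,0.0254873,0.4352463
25,0.200303,0.181325,0.0235625,0.4051905
26,0.176916,0.180818,0.0218461,0.3795801
27,0.156994,0.180305,0.0203091,0.3576081
28,0.139921,0.179789,0.0189276,0.3386376
29,0.12521,0.17927,0.0176814,0.3221614
30,0.112469,0.178748,0.0165536,0.3077706
31,0.101548,0.178226,0.0155296,0.2953036
32,0.0919855,0.177703,0.0145972,0.2842857
33,0.0835775,0.17718,0.0137458,0.2745033
34,0.0761557,0.176658,0.0129663,0.26578
35,0.0695802,0.176136,0.012251,0.2579672
36,0.0637345,0.175616,0.011593,0.2509435
37,0.0585204,0.175098,0.0109863,0.2446047
38,0.0538553,0.174582,0.0104258,0.2388631
39,0.0496692,0.174067,0.00990692,0.23364312
40,0.0459024,0.173555,0.00942567,0.22888307
41,0.0425648,0.173046,0.0089785,0.2245893
42,0.0395418,0.172539,0.00856228,0.22064308
43,0.0367972,0.172034,0.00817424,0.21700544
44,0.0342997,0.171533,0.00781188,0.21364458
45,0.0320223,0.171034,0.00747301,0.21052931
46,0.0299414,0.170539,0.00715564,0.20763604
47,0.0280361,0.170046,0.006858,0.2049401
48,0.0262884,0.169556,0.00657849,0.20242289
49,0.0246824,0.16907,0.00631567,0.20006807
50,0.0232041,0.168586,0.00606824,0.19785834
51,0.0219022,0.168106,0.00583502,0.19584322
52,0.0206965,0.167629,0.00561496,0.19394046
53,0.0195783,0.167155,0.00540709,0.19214039
54,0.0185398,0.166684,0.00521051,0.19043431
55,0.0175739,0.166216,0.00502443,0.18881433
56,0.0166744,0.165752,0.00484812,0.18727452
57,0.0158356,0.165291,0.00468091,0.18580751
58,0.0150526,0.164832,0.00452218,0.18440678
59,0.0143207,0.164378,0.00437137,0.18307007
60,0.0136358,0.163926,0.00422797,0.18178977
61,0.0129967,0.163477,0.00409149,0.18056519
62,0.0123972,0.163031,0.00396149,0.17938969
63,0.0118343,0.162589,0.00383759,0.17826089
64,0.0113053,0.162149,0.00371939,0.17717369
65,0.0108075,0.161713,0.00360657,0.17612707
66,0.0103388,0.16128,0.00349878,0.17511758
67,0.00989698,0.16085,0.00339575,0.17414273
68,0.0094802,0.160422,0.0032972,0.1731994
69,0.00908666,0.159998,0.00320287,0.17228753
70,0.00871478,0.159577,0.00311252,0.1714043
71,0.00836308,0.159158,0.00302593,0.17054701
72,0.00803019,0.158743,0.00294291,0.1697161
73,0.00771488,0.15833,0.00286324,0.16890812
74,0.00741599,0.15792,0.00278677,0.16812276
75,0.00713246,0.157514,0.00271331,0.16735977
76,0.00686331,0.15711,0.00264271,0.16661602
77,0.00660764,0.156708,0.00257483,0.16589047
78,0.00636461,0.15631,0.00250953,0.16518414
79,0.00613345,0.155914,0.00244668,0.16449413
80,0.00591343,0.155521,0.00238615,0.16382058
81,0.00570825,0.155131,0.00232784,0.16316709
82,0.00551258,0.154743,0.00227164,0.16252722
83,0.00532587,0.154358,0.00221745,0.16190132
84,0.0051476,0.153975,0.00216517,0.16128777
85,0.0049773,0.153596,0.00211472,0.16068802
86,0.00481454,0.153218,0.00206601,0.16009855
87,0.00465888,0.152844,0.00201896,0.15952184
88,0.00450996,0.152472,0.00197349,0.15895545
89,0.00436739,0.152102,0.00192954,0.15839893
90,0.00423085,0.151735,0.00188705,0.1578529
91,0.00410002,0.15137,0.00184594,0.15731596
92,0.0039746,0.151008,0.00180616,0.15678876
93,0.00385431,0.150648,0.00176764,0.15626995
94,0.00373889,0.15029,0.00173035,0.15575924
95,0.00362809,0.149935,0.00169422,0.15525731
96,0.00352168,0.149582,0.00165921,0.15476289
97,0.00341945,0.149232,0.00162528,0.15427673
98,0.00332119,0.148884,0.00159237,0.15379756
99,0.00322671,0.148538,0.00156045,0.15332516
100,0.00313583,0.148194,0.00152948,0.15285931
101,0.00305805,0.147853,0.00149942,0.15241047
102,0.00298294,0.147514,0.00147024,0.15196718
103,0.00291037,0.147176,0.00144191,0.15152828
104,0.00284025,0.146842,0.00141438,0.15109663
105,0.00277247,0.146509,0.00138763,0.1506691
106,0.00270692,0.146178,0.00136163,0.15024655
107,0.00264352,0.14585,0.00133636,0.14982988
108,0.00258217,0.145523,0.00131178,0.14941695
109,0.00252279,0.145199,0.00128788,0.14900967
110,0.0024653,0.144877,0.00126462,0.14860692
111,0.00240962,0.144557,0.00124199,0.14820861
112,0.00235568,0.144238,0.00121995,0.14781363
113,0.00230341,0.143922,0.0011985,0.14742391
114,0.00225275,0.143608,0.00117761,0.14703836
115,0.00220363,0.143295,0.00115726,0.14665589
116,0.00215599,0.142985,0.00113743,0.14627842
117,0.00210978,0.142677,0.0011181,0.14590488
118,0.00206494,0.14237,0.00109927,0.14553421
119,0.00202142,0.142065,0.00108091,0.14516733
120,0.00197917,0.141762,0.001063,0.14480417
121,0.00193814,0.141461,0.00104553,0.14444467
122,0.00189829,0.141162,0.00102849,0.14408878
123,0.00185958,0.140865,0.00101186,0.14373644
124,0.00182195,0.140569,0.000995634,0.143386584
125,0.00178539,0.140275,0.000979793,0.143040183
126,0.00174984,0.139983,0.000964327,0.142697167
127,0.00171526,0.139693,0.000949224,0.142357484
128,0.00168164,0.139404,0.000934473,0.142020113
129,0.00164893,0.139117,0.000920062,0.141685992
130,0.0016171,0.138832,0.000905982,0.141355082
131,0.00158612,0.138549,0.000892223,0.141027343
132,0.00155597,0.138267,0.000878775,0.140701745
133,0.0015266,0.137987,0.000865628,0.140379228
134,0.00149801,0.137708,0.000852773,0.140058783
135,0.00147016,0.137431,0.000840203,0.139741363
136,0.00144302,0.137156,0.000827908,0.139426928
137,0.00141658,0.136882,0.000815881,0.139114461
138,0.00139082,0.13661,0.000804114,0.138804934
139,0.0013657,0.136339,0.0007926,0.1384973
140,0.00134121,0.13607,0.000781331,0.138192541
141,0.00131733,0.135803,0.0007703,0.13789063
142,0.00129404,0.135537,0.000759502,0.137590542
143,0.00127132,0.135272,0.000748928,0.137292248
144,0.00124915,0.135009,0.000738574,0.136996724
145,0.00122752,0.134748,0.000728432,0.136703952
146,0.00120641,0.134488,0.000718498,0.136412908
147,0.0011858,0.134229,0.000708766,0.136123566
148,0.00116568,0.133972,0.00069923,0.13583691
149,0.00114603,0.133716,0.000689885,0.135551915
150,0.00112684,0.133462,0.000680726,0.135269566
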