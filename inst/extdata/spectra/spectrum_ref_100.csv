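# synthetic reference spectrum, 100 kVp tungsten anode
# 12 deg anode, 2.5 mm Al total filtration, 0.5 keV bins
# produced by data-raw/make_reference_spectra.R
energy_keV,fluence
1.25,0
1.75,0
2.25,0
2.75,0
3.25,2.65574e-235
3.75,2.82756e-155
4.25,7.79248e-108
4.75,6.02736e-78
5.25,3.15637e-58
5.75,1.09682e-44
6.25,4.27342e-35
6.75,4.23392e-28
7.25,7.02574e-23
7.75,6.78439e-19
8.25,8.40457e-16
8.75,2.33353e-13
9.25,2.09698e-11
9.75,8.01848e-10
10.25,2.89443e-09
10.75,1.4366e-08
11.25,1.39623e-07
11.75,2.08063e-07
12.25,6.4367e-07
12.75,2.88511e-06
13.25,1.13937e-05
13.75,3.72441e-05
14.25,0.000103851
14.75,0.000253418
15.25,0.000557097
15.75,0.00111758
16.25,0.00205854
16.75,0.00352515
17.25,0.00566841
17.75,0.00863346
18.25,0.0125433
18.75,0.0174916
19.25,0.0235316
19.75,0.0306778
20.25,0.0388465
20.75,0.0479557
21.25,0.0579578
21.75,0.0687402
22.25,0.0801718
22.75,0.0921161
23.25,0.10443
23.75,0.116978
24.25,0.129624
24.75,0.142248
25.25,0.154735
25.75,0.166988
26.25,0.178919
26.75,0.190455
27.25,0.201535
27.75,0.21211
28.25,0.222141
28.75,0.231601
29.25,0.240471
29.75,0.248739
30.25,0.256494
30.75,0.263732
31.25,0.270361
31.75,0.276391
32.25,0.281835
32.75,0.28671
33.25,0.291037
33.75,0.294834
34.25,0.298126
34.75,0.300933
35.25,0.303281
35.75,0.305192
36.25,0.306689
36.75,0.307796
37.25,0.308536
37.75,0.30893
38.25,0.309
38.75,0.308767
39.25,0.308252
39.75,0.307472
40.25,0.306454
40.75,0.305213
41.25,0.30376
41.75,0.30211
42.25,0.300278
42.75,0.298277
43.25,0.296123
43.75,0.293826
44.25,0.291399
44.75,0.288853
45.25,0.286199
45.75,0.283447
46.25,0.280605
46.75,0.277682
47.25,0.274688
47.75,0.271627
48.25,0.26851
48.75,0.26534
49.25,0.262126
49.75,0.258871
50.25,0.255582
50.75,0.252261
51.25,0.248916
51.75,0.245551
52.25,0.24217
52.75,0.238776
53.25,0.235373
53.75,0.231964
54.25,0.228552
54.75,0.22514
55.25,0.22173
55.75,0.218324
56.25,0.214925
56.75,0.211534
57.25,0.208153
57.75,0.663863
58.25,0.201429
58.75,0.198089
59.25,1
59.75,0.191457
60.25,0.188167
60.75,0.184894
61.25,0.181642
61.75,0.178411
62.25,0.175201
62.75,0.172014
63.25,0.16885
63.75,0.165709
64.25,0.162592
64.75,0.159499
65.25,0.156431
65.75,0.153387
66.25,0.150369
66.75,0.147376
67.25,0.422503
67.75,0.141465
68.25,0.138549
68.75,0.135657
69.25,0.206681
69.75,0.121056
70.25,0.118727
70.75,0.116401
71.25,0.114078
71.75,0.111761
72.25,0.109449
72.75,0.107143
73.25,0.104844
73.75,0.102553
74.25,0.10027
74.75,0.0979965
75.25,0.095732
75.75,0.0934774
76.25,0.0912332
76.75,0.0889996
77.25,0.0867773
77.75,0.0845664
78.25,0.0823674
78.75,0.0801806
79.25,0.0780062
79.75,0.0758444
80.25,0.073695
80.75,0.0715581
81.25,0.0694347
81.75,0.067325
82.25,0.065229
82.75,0.0631469
83.25,0.0610788
83.75,0.0590248
84.25,0.0569849
84.75,0.0549594
85.25,0.0529481
85.75,0.0509512
86.25,0.0489687
86.75,0.0470005
87.25,0.0450469
87.75,0.0431076
88.25,0.0411828
88.75,0.0392724
89.25,0.0373765
89.75,0.0354948
90.25,0.0336276
90.75,0.0317746
91.25,0.0299359
91.75,0.0281115
92.25,0.0263012
92.75,0.024505
93.25,0.0227229
93.75,0.0209547
94.25,0.0192005
94.75,0.0174601
95.25,0.0157334
95.75,0.0140205
96.25,0.0123211
96.75,0.0106353
97.25,0.00896285
97.75,0.00730377
98.25,0.00565794
98.75,0.00402526
99.25,0.00240565
99.75,0.000799004
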