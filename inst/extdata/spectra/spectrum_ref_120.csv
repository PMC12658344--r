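# synthetic reference spectrum, 120 kVp tungsten anode
# 12 deg anode, 2.5 mm Al total filtration, 0.5 keV bins
# produced by data-raw/make_reference_spectra.R
energy_keV,fluence
1.25,0
1.75,0
2.25,0
2.75,0
3.25,7.54627e-236
3.75,8.53551e-156
4.25,2.45702e-108
4.75,1.96378e-78
5.25,1.05474e-58
5.75,3.73977e-45
6.25,1.48102e-35
6.75,1.48724e-28
7.25,2.49586e-23
7.75,2.43338e-19
8.25,3.03949e-16
8.75,8.50038e-14
9.25,7.68765e-12
9.75,2.95651e-10
10.25,1.05521e-09
10.75,5.09584e-09
11.25,4.99205e-08
11.75,7.24421e-08
12.25,2.22737e-07
12.75,1.00485e-06
13.25,4.00183e-06
13.75,1.31832e-05
14.25,3.70247e-05
14.75,9.0952e-05
15.25,0.00020119
15.75,0.000405953
16.25,0.00075184
16.75,0.00129411
17.25,0.00209103
17.75,0.00319948
18.25,0.00466874
18.75,0.00653769
19.25,0.0088302
19.75,0.0115557
20.25,0.0146864
20.75,0.0181944
21.25,0.0220643
21.75,0.0262554
22.25,0.0307196
22.75,0.0354059
23.25,0.0402601
23.75,0.04523
24.25,0.0502636
24.75,0.0553134
25.25,0.0603347
25.75,0.0652881
26.25,0.0701383
26.75,0.0748555
27.25,0.0794138
27.75,0.0837928
28.25,0.0879756
28.75,0.0919496
29.25,0.0957055
29.75,0.0992373
30.25,0.10258
30.75,0.10573
31.25,0.108648
31.75,0.111337
32.25,0.113801
32.75,0.116045
33.25,0.118076
33.75,0.1199
34.25,0.121526
34.75,0.122961
35.25,0.124215
35.75,0.125294
36.25,0.126209
36.75,0.126967
37.25,0.127577
37.75,0.128048
38.25,0.128386
38.75,0.128602
39.25,0.128701
39.75,0.128691
40.25,0.128583
40.75,0.128383
41.25,0.128093
41.75,0.127721
42.25,0.127271
42.75,0.12675
43.25,0.126162
43.75,0.125513
44.25,0.124808
44.75,0.12405
45.25,0.123244
45.75,0.122393
46.25,0.121503
46.75,0.120575
47.25,0.119614
47.75,0.118622
48.25,0.117603
48.75,0.116558
49.25,0.115491
49.75,0.114403
50.25,0.113297
50.75,0.112174
51.25,0.111037
51.75,0.109888
52.25,0.108729
52.75,0.10756
53.25,0.106384
53.75,0.105202
54.25,0.104015
54.75,0.102824
55.25,0.10163
55.75,0.100435
56.25,0.0992387
56.75,0.0980425
57.25,0.0968471
57.75,0.613074
58.25,0.0944618
58.75,0.0932732
59.25,1
59.75,0.0909067
60.25,0.0897293
60.75,0.088556
61.25,0.0873883
61.75,0.0862263
62.25,0.0850705
62.75,0.0839211
63.25,0.0827785
63.75,0.0816428
64.25,0.0805143
64.75,0.0793933
65.25,0.0782799
65.75,0.0771742
66.25,0.0760765
66.75,0.0749867
67.25,0.388032
67.75,0.0728319
68.25,0.0717669
68.75,0.0707104
69.25,0.153153
69.75,0.0622067
70.25,0.0614424
70.75,0.0606762
71.25,0.0599086
71.75,0.05914
72.25,0.0583707
72.75,0.057601
73.25,0.0568315
73.75,0.0560622
74.25,0.0552936
74.75,0.054526
75.25,0.0537595
75.75,0.0529944
76.25,0.052231
76.75,0.0514695
77.25,0.05071
77.75,0.0499528
78.25,0.0491981
78.75,0.048446
79.25,0.0476967
79.75,0.0469502
80.25,0.0462063
80.75,0.0454651
81.25,0.0447273
81.75,0.043993
82.25,0.0432623
82.75,0.0425353
83.25,0.041812
83.75,0.0410926
84.25,0.0403771
84.75,0.0396655
85.25,0.038958
85.75,0.0382546
86.25,0.0375553
86.75,0.0368602
87.25,0.0361693
87.75,0.0354826
88.25,0.0348003
88.75,0.0341222
89.25,0.0334485
89.75,0.0327791
90.25,0.0321141
90.75,0.0314534
91.25,0.0307972
91.75,0.0301453
92.25,0.0294978
92.75,0.0288548
93.25,0.0282161
93.75,0.0275819
94.25,0.026952
94.75,0.0263265
95.25,0.0257054
95.75,0.0250887
96.25,0.0244764
96.75,0.0238684
97.25,0.0232647
97.75,0.0226654
98.25,0.0220704
98.75,0.0214796
99.25,0.0208931
99.75,0.0203109
100.25,0.0197329
100.75,0.0191591
101.25,0.0185895
101.75,0.0180241
102.25,0.0174628
102.75,0.0169056
103.25,0.0163525
103.75,0.0158034
104.25,0.0152584
104.75,0.0147174
105.25,0.0141804
105.75,0.0136474
106.25,0.0131183
106.75,0.0125931
107.25,0.0120717
107.75,0.0115543
108.25,0.0110406
108.75,0.0105307
109.25,0.0100247
109.75,0.0095223
110.25,0.00902366
110.75,0.00852869
111.25,0.00803738
111.75,0.0075497
112.25,0.0070656
112.75,0.00658507
113.25,0.00610808
113.75,0.00563459
114.25,0.00516458
114.75,0.00469802
115.25,0.00423488
115.75,0.00377513
116.25,0.00331875
116.75,0.00286569
117.25,0.00241594
117.75,0.00196947
118.25,0.00152624
118.75,0.00108624
119.25,0.000649424
119.75,0.000215773
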