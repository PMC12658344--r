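# synthetic reference spectrum, 80 kVp tungsten anode
# 12 deg anode, 2.5 mm Al total filtration, 0.5 keV bins
# produced by data-raw/make_reference_spectra.R
energy_keV,fluence
1.25,0
1.75,0
2.25,0
2.75,0
3.25,1.53579e-234
3.75,1.49329e-154
4.25,3.85499e-107
4.75,2.83866e-77
5.25,1.43112e-57
5.75,4.82477e-44
6.25,1.83437e-34
6.75,1.78097e-27
7.25,2.90569e-22
7.75,2.76561e-18
8.25,3.38371e-15
8.75,9.29298e-13
9.25,8.27083e-11
9.75,3.13534e-09
10.25,1.15217e-08
10.75,5.95226e-08
11.25,5.7161e-07
11.75,8.86318e-07
12.25,2.76719e-06
12.75,1.22818e-05
13.25,4.78889e-05
13.75,0.000154713
14.25,0.000426731
14.75,0.00103082
15.25,0.00224477
15.75,0.00446349
16.25,0.00815352
16.75,0.0138533
17.25,0.0221111
17.75,0.0334403
18.25,0.048259
18.75,0.0668668
19.25,0.089405
19.75,0.11587
20.25,0.145889
20.75,0.179107
21.25,0.215311
21.75,0.254048
22.25,0.294808
22.75,0.337072
23.25,0.380307
23.75,0.424009
24.25,0.467695
24.75,0.510932
25.25,0.553324
25.75,0.594534
26.25,0.634269
26.75,0.672288
27.25,0.708398
27.75,0.742449
28.25,0.774332
28.75,0.803973
29.25,0.831329
29.75,0.856387
30.25,0.879464
30.75,0.900563
31.25,0.919402
31.75,0.936037
32.25,0.95054
32.75,0.962985
33.25,0.97346
33.75,0.982051
34.25,0.988851
34.75,0.993952
35.25,0.99745
35.75,0.999434
36.25,1
36.75,0.999234
37.25,0.997223
37.75,0.994052
38.25,0.989801
38.75,0.984548
39.25,0.978367
39.75,0.971328
40.25,0.963518
40.75,0.954995
41.25,0.945802
41.75,0.935993
42.25,0.925623
42.75,0.914742
43.25,0.903397
43.75,0.891632
44.25,0.879489
44.75,0.867006
45.25,0.854221
45.75,0.841165
46.25,0.827872
46.75,0.81437
47.25,0.800687
47.75,0.786847
48.25,0.772875
48.75,0.758791
49.25,0.744617
49.75,0.730371
50.25,0.716065
50.75,0.701716
51.25,0.687344
51.75,0.672962
52.25,0.658583
52.75,0.644217
53.25,0.629877
53.75,0.61557
54.25,0.601307
54.75,0.587095
55.25,0.572942
55.75,0.558854
56.25,0.544837
56.75,0.530897
57.25,0.517039
57.75,0.705578
58.25,0.489587
58.75,0.476001
59.25,0.81717
59.75,0.449124
60.25,0.435835
60.75,0.422649
61.25,0.409571
61.75,0.396602
62.25,0.383745
62.75,0.371
63.25,0.358369
63.75,0.345852
64.25,0.33345
64.75,0.321163
65.25,0.308992
65.75,0.296937
66.25,0.284998
66.75,0.273174
67.25,0.383617
67.75,0.249874
68.25,0.238397
68.75,0.227034
69.25,0.248224
69.75,0.198593
70.25,0.188272
70.75,0.178006
71.25,0.167798
71.75,0.15765
72.25,0.147563
72.75,0.137539
73.25,0.12758
73.75,0.117688
74.25,0.107863
74.75,0.0981063
75.25,0.0884197
75.75,0.0788036
76.25,0.0692589
76.75,0.0597863
77.25,0.0503863
77.75,0.0410594
78.25,0.0318061
78.75,0.0226267
79.25,0.0135214
79.75,0.0044905
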