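# mass energy-absorption coefficient of dry air, cm^2/g
# standard-grid dosimetry values; Ar K edge at 3.206 keV duplicated
energy_keV,muen_over_rho
1,3599
1.5,1188
2,526.2
3,161.4
3.206,133
3.206,136
4,76.36
5,39.31
6,22.7
8,9.446
10,4.742
15,1.334
20,0.5389
30,0.1537
40,0.06833
50,0.04098
60,0.03041
80,0.02407
100,0.02325
150,0.02496
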