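# Synthetic Y-90-like radial dose-point kernel (relative energy density vs radius).
# Analytic stand-in constructed for this package: smooth monotone profile
# rho(r) = exp(-r/2.2 mm) * (1 - r/11.3 mm), cut off at the 11.3 mm Y-90
# maximum beta range in soft tissue. NOT a Monte-Carlo transport result.
# The convolution engine renormalizes the discretized kernel to sum to 1.
radius_mm	rel_energy_density
0.0	1.00000000
0.1	0.94710673
0.2	0.89693964
0.3	0.84936090
0.4	0.80423954
0.5	0.76145110
0.6	0.72087736
0.7	0.68240596
0.8	0.64593020
0.9	0.61134867
1.0	0.57856505
1.1	0.54748785
1.2	0.51803014
1.3	0.49010936
1.4	0.46364709
1.5	0.43856883
1.6	0.41480383
1.7	0.39228491
1.8	0.37094824
1.9	0.35073322
2.0	0.33158230
2.1	0.31344082
2.2	0.29625690
2.3	0.27998124
2.4	0.26456706
2.5	0.24996993
2.6	0.23614769
2.7	0.22306028
2.8	0.21066969
2.9	0.19893983
3.0	0.18783646
3.1	0.17732706
3.2	0.16738075
3.3	0.15796825
3.4	0.14906177
3.5	0.14063490
3.6	0.13266262
3.7	0.12512117
3.8	0.11798799
3.9	0.11124170
4.0	0.10486199
4.1	0.09882961
4.2	0.09312628
4.3	0.08773468
4.4	0.08263836
4.5	0.07782172
4.6	0.07326998
4.7	0.06896910
4.8	0.06490577
4.9	0.06106738
5.0	0.05744195
5.1	0.05401815
5.2	0.05078520
5.3	0.04773291
5.4	0.04485161
5.5	0.04213212
5.6	0.03956576
5.7	0.03714429
5.8	0.03485989
5.9	0.03270518
6.0	0.03067312
6.1	0.02875708
6.2	0.02695075
6.3	0.02524818
6.4	0.02364370
6.5	0.02213197
6.6	0.02070790
6.7	0.01936668
6.8	0.01810378
6.9	0.01691488
7.0	0.01579588
7.1	0.01474294
7.2	0.01375238
7.3	0.01282075
7.4	0.01194476
7.5	0.01112131
7.6	0.01034745
7.7	0.00962041
7.8	0.00893755
7.9	0.00829638
8.0	0.00769454
8.1	0.00712981
8.2	0.00660008
8.3	0.00610335
8.4	0.00563773
8.5	0.00520144
8.6	0.00479279
8.7	0.00441019
8.8	0.00405213
8.9	0.00371719
9.0	0.00340400
9.1	0.00311132
9.2	0.00283792
9.3	0.00258268
9.4	0.00234452
9.5	0.00212242
9.6	0.00191543
9.7	0.00172265
9.8	0.00154322
9.9	0.00137634
10.0	0.00122123
10.1	0.00107720
10.2	0.00094355
10.3	0.00081966
10.4	0.00070491
10.5	0.00059875
10.6	0.00050062
10.7	0.00041004
10.8	0.00032651
10.9	0.00024960
11.0	0.00017888
11.1	0.00011396
11.2	0.00005445
11.3	0.00000000
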