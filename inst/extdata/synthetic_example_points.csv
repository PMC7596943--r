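"time","s1","s2"
0,1,1
0.5,0.975,0.992
0.8,0.949,0.983
1.3,0.924,0.983
1.8,0.915,0.957
2.8,0.89,0.957
3.3,0.863,0.957
3.6,0.837,0.957
3.9,0.811,0.948
4.9,0.793,0.921
5.9,0.767,0.912
6.5,0.74,0.903
7.2,0.714,0.903
7.5,0.705,0.875
8.4,0.705,0.847
9.1,0.678,0.837
9.4,0.651,0.837
10.3,0.624,0.827
11.8,0.595,0.817
12.6,0.566,0.808
13.5,0.557,0.787
14.3,0.547,0.767
15.9,0.518,0.767
16.5,0.489,0.767
17.5,0.479,0.746
18.7,0.469,0.724
20.9,0.44,0.714
21.2,0.41,0.702
21.9,0.401,0.679
23,0.371,0.667
24.1,0.371,0.644
26.1,0.362,0.62
27.7,0.351,0.595
29.1,0.329,0.583
29.5,0.307,0.583
29.9,0.284,0.583
30.8,0.284,0.556
32.3,0.272,0.53
34.2,0.247,0.516
35.5,0.22,0.503
39.1,0.207,0.475
40.5,0.207,0.448
42,0.192,0.42
43.3,0.162,0.42
45.7,0.133,0.405
53.1,0.101,0.39
57.5,0.101,0.36
60,0.101,0.345
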