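0.042
0.205
0.285
0.319
0.464
0.550
0.889
0.895
0.939
0.986
1.000
1.088
1.212
1.244
1.450
1.593
1.844
2.039
2.157
2.167
2.334
2.440
2.657
3.685
3.879
4.493
4.800
4.944
5.155
5.674
7.602
10.004
12.238
12.520
12.553
13.063
15.105
15.229
15.629
15.848
18.641
18.940
29.885
58.162
61.838
72.286
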