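run_id,t_c,tmp_bar,conc_kgm3,x1,x2,x3,sf,ji
1,45,3,100,0,0,0,2.80,1.350
2,30,1,100,-1,-1,0,1.75,0.270
3,45,3,100,0,0,0,2.74,1.660
4,60,3,50,1,0,-1,2.30,1.010
5,30,3,150,-1,0,1,1.80,1.130
6,60,1,100,1,-1,0,1.91,0.630
7,60,3,150,1,0,1,2.25,2.220
8,60,5,100,1,1,0,2.30,2.600
9,30,5,100,-1,1,0,1.97,1.350
10,45,5,50,0,1,-1,2.28,0.800
11,45,5,150,0,1,1,2.14,1.510
12,45,3,100,0,0,0,2.60,1.230
13,45,1,150,0,-1,1,1.90,0.790
14,45,1,50,0,-1,-1,2.22,0.380
15,30,3,50,-1,0,-1,2.34,0.560
16,45,3,100,0,0,0,2.70,1.110
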