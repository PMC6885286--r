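"time_min","a234"
0,0.00091
5,0.05432
10,0.10932
15,0.16424
20,0.21881
25,0.27362
30,0.3291
35,0.33149
40,0.33434
45,0.3379
50,0.3399
55,0.34359
60,0.34615
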