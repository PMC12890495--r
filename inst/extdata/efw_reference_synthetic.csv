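"ga_weeks","mean_g","sd_g"
20,331,42
21,399,51
22,478,61
23,568,72
24,670,85
25,785,100
26,913,116
27,1055,134
28,1210,154
29,1379,175
30,1559,198
31,1751,222
32,1953,248
33,2162,275
34,2377,302
35,2595,330
36,2813,357
37,3028,385
38,3236,411
39,3435,436
40,3619,460
41,3787,481
42,3934,500
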