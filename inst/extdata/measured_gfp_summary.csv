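aTc_ng_ml,n_cells,mean,sd
0,245,1841.54,2414.88
0.1,225,5526.12,3901.75
0.5,88,16948.61,8781.03
1,203,73338.24,33388.72
2,299,231836.5,105391.2
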