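scenario,u_mean_cyclic_max,u_mean_cyclic_mean,oop_ratio
noFD,0.153,0.119,0.036
FDC1,0.031,0.026,0.052
FDC2,0.026,0.021,0.045
FDC3,0.017,0.013,0.364
FDC4,0.047,0.043,0.368
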