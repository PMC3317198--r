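time_h,lc50,ci_low,ci_high
24,1.039,0.245,1.288
48,0.792,0.622,0.962
72,0.734,0.561,0.908
96,0.655,0.488,0.823
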