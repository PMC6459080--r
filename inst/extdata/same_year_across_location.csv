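trait,year,r_pv
DLmix,2017,0.45
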