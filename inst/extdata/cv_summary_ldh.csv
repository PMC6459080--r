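trait,year,r_pv,H2
LOI,2016,0.30,0.59
LOS,2016,0.31,0.50
LI,2016,0.32,0.55
DLmean,2016,0.35,0.56
DLmix,2016,0.31,0.52
LOI,2017,0.41,0.67
LOS,2017,0.41,0.63
LI,2017,0.40,0.63
DLmean,2017,0.40,0.71
DLmix,2017,0.42,0.63
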