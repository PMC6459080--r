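trait,ldh16_ldh17,ldh17_ldh16,ldh16_fas17,ldh17_fas16
LOI,0.37,0.45,0.28,0.27
LOS,0.42,0.54,0.32,0.23
LI,0.39,0.49,0.27,0.21
DLmean,0.37,0.51,0.30,0.20
DLmix,0.38,0.55,0.29,0.19
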