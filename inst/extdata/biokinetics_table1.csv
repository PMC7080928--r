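organ,time_h,percent_ia_per_g,dose_rate_mGy_per_h
testis,4,0.36,4.6
testis,25,0.28,3.8
liver,4,7.63,117
liver,25,7.0,102
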