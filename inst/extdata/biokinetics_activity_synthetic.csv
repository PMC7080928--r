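organ,time_h,activity_MBq,organ_mass_g
testis,4,0.022680,0.1
testis,25,0.017640,0.1
liver,4,7.210350,1.5
liver,25,6.615000,1.5
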