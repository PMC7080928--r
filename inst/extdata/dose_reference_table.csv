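organ,T_eff_h,dose_rate_4h_mGy_per_h,dose_rate_25h_mGy_per_h,dose_per_ia_4h_mGy_per_MBq,dose_per_ia_25h_mGy_per_MBq,dose_per_ia_inf_mGy_per_MBq
testis,58.7,4.6,3.8,0.31,1.65,6.5
liver,167.9,117,102,7.75,49.6,207.1
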