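name,intercept_c,weight_exp_a,height_exp_b,mean_lbsi,sd_lbsi
korean_kns_2018,-2.69,0.73,-1.06,-0.02,0.06
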