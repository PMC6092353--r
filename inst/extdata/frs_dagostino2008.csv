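version_id,sex,term,value
dagostino2008_general_cvd,male,log_age,3.06117
dagostino2008_general_cvd,male,log_tc,1.12370
dagostino2008_general_cvd,male,log_hdl,-0.93263
dagostino2008_general_cvd,male,log_sbp_untreated,1.93303
dagostino2008_general_cvd,male,log_sbp_treated,1.99881
dagostino2008_general_cvd,male,smoker,0.65451
dagostino2008_general_cvd,male,diabetes,0.57367
dagostino2008_general_cvd,male,s0_10yr,0.88936
dagostino2008_general_cvd,male,mean_lp,23.9802
dagostino2008_general_cvd,female,log_age,2.32888
dagostino2008_general_cvd,female,log_tc,1.20904
dagostino2008_general_cvd,female,log_hdl,-0.70833
dagostino2008_general_cvd,female,log_sbp_untreated,2.76157
dagostino2008_general_cvd,female,log_sbp_treated,2.82263
dagostino2008_general_cvd,female,smoker,0.52873
dagostino2008_general_cvd,female,diabetes,0.69154
dagostino2008_general_cvd,female,s0_10yr,0.95012
dagostino2008_general_cvd,female,mean_lp,26.1931
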