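parameter,family,cv,assumed
utility_mrs,beta,0.10,TRUE
utility_decrement,beta,0.20,TRUE
cost_index_evt,gamma,0.15,TRUE
cost_index_medical,gamma,0.15,TRUE
cost_acute_stroke,gamma,0.15,TRUE
cost_mi_hospitalization,gamma,0.15,TRUE
cost_annual_management,gamma,0.15,TRUE
cost_post_mi_annual,gamma,0.15,TRUE
rate_recurrent_stroke,lognormal,0.15,TRUE
rate_mi,lognormal,0.15,TRUE
rate_cvd_death,lognormal,0.15,TRUE
p_fatal_recurrent_stroke,beta,0.15,TRUE
p_fatal_mi,beta,0.15,TRUE
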