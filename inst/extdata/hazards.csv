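event,distribution,rate,shape,risk,risk_horizon_years,source,assumed
recurrent_stroke,exponential,0.04,,,,long-term recurrence literature class,TRUE
recurrent_stroke_alt,gompertz,0.04,0.05,,,sensitivity alternative to the exponential recurrence process,TRUE
mi_vascular_combined,exponential,,,0.174,5,post-stroke cohort composite 5-year MI-or-vascular-death risk,FALSE
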