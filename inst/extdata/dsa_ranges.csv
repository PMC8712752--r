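parameter,low,high
horizon_years,5,25
discount_rate,0,0.05
p_fatal_recurrent_stroke,0.10,0.30
cost_acute_stroke_scale,0.5,1.5
rate_recurrent_stroke,0.02,0.06
utility_decrement,0,0.25
cost_index_evt,24000,40000
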