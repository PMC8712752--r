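parameter,value,source,assumed
p_fatal_recurrent_stroke,0.20,recurrent-stroke case-fatality literature class,TRUE
p_fatal_mi,0.25,post-stroke MI case-fatality literature class,TRUE
mi_fraction,0.50,share of the combined MI/vascular-death process attributed to MI,TRUE
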