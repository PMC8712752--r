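item,state,value,source,assumed
utility,0,0.95,post-stroke utility weight by mRS literature class,TRUE
utility,1,0.93,post-stroke utility weight by mRS literature class,TRUE
utility,2,0.83,post-stroke utility weight by mRS literature class,TRUE
utility,3,0.62,post-stroke utility weight by mRS literature class,TRUE
utility,4,0.42,post-stroke utility weight by mRS literature class,TRUE
utility,5,0.11,post-stroke utility weight by mRS literature class,TRUE
utility,6,0,death,FALSE
event_decrement,,0.125,utility decrement applied after a CVD event,TRUE
decrement_duration,,1,years the post-event decrement persists,TRUE
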