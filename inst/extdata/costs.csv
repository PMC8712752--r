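item,state,value,source,assumed
index_acute,EVT,32000,index hospitalization incl. thrombectomy procedure (AUD 2018),TRUE
index_acute,medical,14000,index hospitalization medical management (AUD 2018),TRUE
acute_recurrent_stroke,0,6000,acute care by recurrent-stroke severity (AUD 2018),TRUE
acute_recurrent_stroke,1,7500,acute care by recurrent-stroke severity (AUD 2018),TRUE
acute_recurrent_stroke,2,9500,acute care by recurrent-stroke severity (AUD 2018),TRUE
acute_recurrent_stroke,3,13000,acute care by recurrent-stroke severity (AUD 2018),TRUE
acute_recurrent_stroke,4,18000,acute care by recurrent-stroke severity (AUD 2018),TRUE
acute_recurrent_stroke,5,22000,acute care by recurrent-stroke severity (AUD 2018),TRUE
acute_recurrent_stroke,6,10000,acute care fatal recurrent stroke (AUD 2018),TRUE
mi_hospitalization,,8500,MI rehospitalization (AUD 2018),TRUE
annual_management,0,2000,annual management by mRS (AUD 2018 per year),TRUE
annual_management,1,2500,annual management by mRS (AUD 2018 per year),TRUE
annual_management,2,3500,annual management by mRS (AUD 2018 per year),TRUE
annual_management,3,6500,annual management by mRS (AUD 2018 per year),TRUE
annual_management,4,12000,annual management by mRS (AUD 2018 per year),TRUE
annual_management,5,20000,annual management by mRS (AUD 2018 per year),TRUE
annual_management,6,0,no management cost after death,FALSE
post_mi_annual,,1300,additional annual management after MI (AUD 2018 per year),TRUE
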