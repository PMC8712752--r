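# Synthetic registry specification: per-arm marginals of the late-window
# (>4.5 h onset-to-imaging) large-vessel-occlusion cohort. Eight matched
# strategy arms (EVT / medical x DEFUSE 3 / DAWN x positive / negative).
# Volumes in ml, age in years, onset_to_ctp in minutes. mrs_counts are the
# 3-month modified Rankin Scale counts (states 0..6) used as sampling
# probabilities after normalisation.
age_bounds: [18, 100]
onset_bounds: [270, 1440]
volume_cap_ml: 600   # anatomical ceiling applied to generated lesion volumes
arms:
  EVT_DEFUSE3_pos:
    size: 105
    treatment_group: EVT
    age: {mean: 68.0, sd: 15.27}
    male_prop: 0.362
    nihss: {median: 16, q1: 11, q3: 21}
    core: {median: 19, q1: 8, q3: 36}
    penumbra: {median: 90, q1: 62, q3: 117}
    onset_to_ctp: {mean: 322, sd: 86}
    p_ica: 0.333
    treatment_probs: {EVT_plus_tPA: 0.476, EVT_only: 0.524, tPA_only: 0, none: 0}
    mrs_counts: [14, 20, 14, 30, 12, 5, 10]
  EVT_DEFUSE3_neg:
    size: 26
    treatment_group: EVT
    age: {mean: 70.0, sd: 14.16}
    male_prop: 0.308
    nihss: {median: 16, q1: 11, q3: 21}
    core: {median: 91, q1: 73, q3: 126}
    penumbra: {median: 93, q1: 63, q3: 123}
    onset_to_ctp: {mean: 394, sd: 72}
    p_ica: 0.577
    treatment_probs: {EVT_plus_tPA: 0.615, EVT_only: 0.385, tPA_only: 0, none: 0}
    mrs_counts: [2, 3, 3, 5, 3, 1, 9]
  MED_DEFUSE3_pos:
    size: 98
    treatment_group: medical
    age: {mean: 69.9, sd: 13.40}
    male_prop: 0.439
    nihss: {median: 15, q1: 11, q3: 19}
    core: {median: 21, q1: 11, q3: 46}
    penumbra: {median: 83, q1: 51, q3: 124}
    onset_to_ctp: {mean: 403, sd: 79}
    p_ica: 0.286
    treatment_probs: {EVT_plus_tPA: 0, EVT_only: 0, tPA_only: 0.071, none: 0.929}
    mrs_counts: [11, 15, 10, 13, 27, 8, 14]
  MED_DEFUSE3_neg:
    size: 62
    treatment_group: medical
    age: {mean: 68.0, sd: 13.62}
    male_prop: 0.290
    nihss: {median: 14, q1: 8, q3: 19}
    core: {median: 15, q1: 0.1, q3: 76}
    penumbra: {median: 11, q1: 3, q3: 73}
    onset_to_ctp: {mean: 372, sd: 83}
    p_ica: 0.436
    treatment_probs: {EVT_plus_tPA: 0, EVT_only: 0, tPA_only: 0.081, none: 0.919}
    mrs_counts: [12, 13, 2, 9, 8, 7, 11]
  EVT_DAWN_pos:
    size: 91
    treatment_group: EVT
    age: {mean: 65.1, sd: 15.17}
    male_prop: 0.429
    nihss: {median: 17, q1: 14, q3: 21}
    core: {median: 21, q1: 10, q3: 36}
    penumbra: {median: 98, q1: 62, q3: 120}
    onset_to_ctp: {mean: 335, sd: 94}
    p_ica: 0.407
    treatment_probs: {EVT_plus_tPA: 0.472, EVT_only: 0.528, tPA_only: 0, none: 0}
    mrs_counts: [15, 12, 9, 20, 11, 6, 18]
  EVT_DAWN_neg:
    size: 20
    treatment_group: EVT
    age: {mean: 67.3, sd: 17.41}
    male_prop: 0.250
    nihss: {median: 18, q1: 14, q3: 22}
    core: {median: 92, q1: 82, q3: 128}
    penumbra: {median: 99, q1: 88, q3: 125}
    onset_to_ctp: {mean: 387, sd: 92}
    p_ica: 0.600
    treatment_probs: {EVT_plus_tPA: 0.600, EVT_only: 0.400, tPA_only: 0, none: 0}
    mrs_counts: [2, 1, 2, 4, 3, 0, 8]
  MED_DAWN_pos:
    size: 59
    treatment_group: medical
    age: {mean: 69.0, sd: 13.99}
    male_prop: 0.407
    nihss: {median: 17, q1: 13, q3: 20}
    core: {median: 23, q1: 10, q3: 40}
    penumbra: {median: 79, q1: 58, q3: 113}
    onset_to_ctp: {mean: 384, sd: 73}
    p_ica: 0.407
    treatment_probs: {EVT_plus_tPA: 0, EVT_only: 0, tPA_only: 0.068, none: 0.932}
    mrs_counts: [9, 7, 6, 9, 12, 4, 12]
  MED_DAWN_neg:
    size: 35
    treatment_group: medical
    age: {mean: 69.1, sd: 14.79}
    male_prop: 0.371
    nihss: {median: 18, q1: 8, q3: 22}
    core: {median: 76, q1: 19, q3: 95}
    penumbra: {median: 86, q1: 44, q3: 109}
    onset_to_ctp: {mean: 393, sd: 81}
    p_ica: 0.600
    treatment_probs: {EVT_plus_tPA: 0, EVT_only: 0, tPA_only: 0.086, none: 0.914}
    mrs_counts: [4, 4, 1, 3, 4, 9, 10]
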