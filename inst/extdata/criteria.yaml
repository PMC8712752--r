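# Perfusion-imaging eligibility criteria, per the published late-window trial
# imaging rules. All thresholds configurable. Volume caps are strict
# comparisons: "large core" means core_volume > 70 ml exactly, and the DAWN
# core caps use strict less-than.
time_window:
  onset_floor_min: 270      # cohort definition: > 4.5 h after onset
  onset_ceiling_min: 1440
defuse3:
  core_max_ml: 70           # eligible iff core_volume < core_max_ml
  mismatch_ratio_min: 1.8   # perfusion / core
  mismatch_volume_min_ml: 15  # perfusion - core
large_core_ml: 70           # flag: core_volume > 70
dawn:
  nihss_min: 10
  age_elderly: 80
  # clinical-core mismatch groups
  elderly_core_max_ml: 21           # age >= 80, NIHSS >= 10, core < 21
  young_core_max_ml: 31             # age < 80, NIHSS >= 10, core < 31
  young_severe_nihss_min: 20        # age < 80, NIHSS >= 20, core < 51
  young_severe_core_max_ml: 51
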