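# Master configuration. Every value here and in the referenced tables is an
# input to the model and can be overridden by pointing load_parameters() at an
# edited copy. Paths are relative to this file.
files:
  cohort_spec: cohort_spec.yaml
  criteria: criteria.yaml
  hazards: hazards.csv
  mortality: mortality_table.csv
  fatality: fatality.csv
  costs: costs.csv
  utilities: utilities.csv
  psa_manifest: psa_manifest.csv
  dsa_ranges: dsa_ranges.csv
analysis:
  n_patients: 50000        # simulated patients per strategy arm (base case)
  horizon_years: 25        # time horizon from Day 90, years
  discount_rate: 0.03      # per annum, continuous-equivalent, costs and QALYs
  wtp: 50000               # willingness to pay, AUD per QALY
  aud_per_usd: 0.75        # 2018 average exchange rate, reporting only
  mortality_dominance_override: true
# Severity (post-event mRS) distribution for non-fatal recurrent stroke,
# states 0..5. Assumed default; survivors move to max(prior, drawn).
severity_recurrent: [0.10, 0.15, 0.20, 0.25, 0.20, 0.10]
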