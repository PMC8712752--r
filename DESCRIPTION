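Package: evtdes
Title: Cost-Effectiveness of Late-Window Endovascular Thrombectomy by
    Discrete Event Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-level, continuous-time simulation of long-term
    outcomes after large-vessel-occlusion ischemic stroke treated in the
    extended (>4.5 h) time window, and the incremental cost-effectiveness of
    endovascular thrombectomy (EVT) versus medical management inside and
    outside the DEFUSE 3 / DAWN perfusion-imaging criteria. Includes a
    synthetic registry generator calibrated to published cohort marginals,
    trial-criteria classifiers, propensity-score nearest-neighbour matching
    with balance diagnostics, a discrete-event engine for recurrent stroke,
    myocardial infarction and cause-specific death, economic accrual of
    discounted costs and quality-adjusted life years, and deterministic and
    probabilistic sensitivity analyses with cost-effectiveness acceptability
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
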