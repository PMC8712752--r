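---
title: "Modelling long-term outcomes and cost-effectiveness of late-window thrombectomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term outcomes and cost-effectiveness of late-window thrombectomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtdes)
```

## The question

Endovascular thrombectomy (EVT) for large-vessel-occlusion ischemic stroke
in the extended time window (here, presentation more than 4.5 hours after
symptom onset) was established by trials that selected patients with
perfusion imaging: a small ischemic core together with a substantial volume
of salvageable tissue (DEFUSE 3), or a clinical–core mismatch between
stroke severity and core volume (DAWN). In routine care many patients are
treated outside those imaging criteria. This package asks what that "scope
creep" costs: it simulates the long-term consequences of the 3-month
functional outcome (modified Rankin Scale, mRS) observed in criteria-positive
and criteria-negative patients treated with EVT or managed medically, and
computes incremental cost-effectiveness from the perspective of the
Australian healthcare system (AUD 2018, willingness to pay AUD 50,000 per
QALY).

The analysis is organised as five stages, each driven by a script under
`analysis/` and implemented by exported functions: registry synthesis and
criteria classification, propensity matching, discrete-event simulation,
economic accrual, and incremental/sensitivity analysis.

## Synthetic registry

No patient-level data are distributed; the generator emulates a late-window
registry cohort from published per-arm marginals (`cohort_spec.yaml`):

* **age** — truncated normal on [18, 100] from the arm's mean (SD);
* **NIHSS** — a negative binomial fitted by quantile matching to the
  published median (IQR), clipped to 0–42; a skewed discrete severity score
  cannot be represented well by a normal;
* **core and penumbra volumes** — log-normals fitted by quantile matching:
  the median is matched exactly (`meanlog = log(median)`) and the IQR
  through its log-ratio (`sdlog = log(q3/q1)/(2 z_{0.75})`). When the
  printed IQR is asymmetric about the median on the log scale, individual
  quartiles are matched only approximately — an accepted limitation of a
  two-parameter family. The perfusion lesion is **core + penumbra by
  construction**, so the mismatch identity holds exactly; the implied
  perfusion median is then close to, not exactly, the printed value
  (e.g. 19 + 90 = 109 vs 112 printed). Generated volumes are capped at an
  anatomical ceiling (600 ml, configurable), which matters only for the
  criteria-negative medical arm whose printed IQR (0.1–76 ml) implies an
  extremely heavy upper tail;
* **onset-to-imaging** — truncated normal on (270, 1440) minutes, so every
  record satisfies the >4.5 h cohort definition;
* **Day-90 mRS** — a draw from the arm's 7-state probability vector, the
  single most consequential marginal: it fixes the initial health state of
  the long-term simulation.

The classifiers apply the published imaging rules with strict boundary
conventions: "large core" is strictly `core > 70 ml`; DEFUSE 3 requires
core < 70 ml, mismatch ratio ≥ 1.8 and mismatch volume ≥ 15 ml; DAWN uses
the age-banded clinical–core mismatch table (≥80 y: NIHSS ≥ 10 and
core < 21 ml; <80 y: NIHSS ≥ 10 and core < 31 ml, or NIHSS ≥ 20 and
core < 51 ml), all caps strict less-than. A zero perfusion lesion makes the
mismatch ratio undefined; such records are classified ineligible with a
warning rather than an error. All thresholds live in `criteria.yaml`.

What passing the generator's tests does **not** show: real registries have
correlated covariates (age–NIHSS–core are not independent), informative
missingness, and site effects. The generator reproduces marginals only;
conclusions that depend on covariate correlation (e.g. exact matched
counts) are not reproducible from it, and the matching stage is therefore
validated on its own simulations rather than against the source study's
matched/unmatched tallies.

## Propensity matching

Treatment assignment is modelled by logistic regression of EVT on age, sex,
NIHSS and ischemic core volume (premorbid disability is deliberately not a
covariate — it is typically under-recorded in registries). Matching is
greedy nearest-neighbour on the score: treated patients processed in
descending score order, each paired with the unused control minimising the
absolute score difference; defaults are no caliper and no replacement, with
equidistant controls broken by a seeded shuffle. These settings are the
common defaults of registry practice but are not uniquely determined, so
all are arguments. Balance is reported as standardized mean differences
before and after matching; perfect separation in the logistic fit is a
hard error naming the separating covariate (a matched analysis is
meaningless without common support).

## Discrete-event engine

Each simulated patient starts at Day 90 in mRS state 0–6 (state 6 is
death at t = 0, accruing index costs only) and experiences competing
risks in continuous time until death or the horizon (default 25 years):

* **recurrent stroke** — exponential, default 4%/year; a Gompertz
  alternative (`recurrent_stroke_alt`) is exposed for sensitivity analysis;
* **myocardial infarction** and **CVD death** — the combined MI-or-vascular-
  death process is calibrated so its 5-year cumulative incidence is 17.4%
  (`rate = -ln(1-0.174)/5`) and split by a configurable `mi_fraction`
  (default 0.5) into an exponential MI hazard and a constant CVD-death
  hazard. Whether and how the source supplement split and age-modulated
  this composite is unknown; both choices are explicit, flagged
  assumptions;
* **non-CVD death** — an age- and sex-indexed annual-hazard table sampled
  piecewise-exponentially (the hazard is constant within each integer year
  of age; beyond the table the last value is extrapolated, where sampling
  finishes in closed form).

After a non-fatal event the survivor's clocks are re-sampled (memoryless
renewal — no hazard escalation with event history, since history dependence
is not identifiable from the inputs) and age advances continuously. Fatal
outcomes of stroke/MI are Bernoulli with probabilities
`p_fatal_recurrent_stroke` (0.20) and `p_fatal_mi` (0.25). A non-fatal
recurrent stroke draws a severity from a configurable distribution; the
survivor's state becomes `max(prior, drawn)` (functional status does not
improve after a recurrence), while the acute admission is priced by the
drawn severity itself. Simultaneous candidate times (measure zero) resolve
by a fixed priority: non-CVD death, CVD death, stroke, MI, horizon.

The engine is vectorised over patients (round-by-round competing-risk
sampling), which is what makes a 1,000-draw probabilistic sensitivity
analysis with 2,000 patients per arm per draw run in minutes on one core.
`simulate_patient()` is the single-patient trace-keeping wrapper, and
`accrue_trace()` is a deliberately independent per-trace integrator; the
test-suite requires the two accrual routes to agree to 1e-9.

### Calibrating the default mortality table

The packaged non-CVD table is a literature-class stroke-survivor excess
mortality assumption of the form `h(a) = h0 · exp(g (a − 72))` with
`h0 ≈ 0.055/yr` and `g = 0.04/yr`, sex-adjusted ±5%. Two considerations
fixed these two constants at design time:

1. the 5-year survival of the criteria-positive medically managed arm
   should sit near the low-50s percent reported by long-term observational
   stroke cohorts (the validation stage checks the band 45–58%);
2. the **relative** age gradient is flatter than a general-population life
   table because a large excess hazard common to all ages dominates
   post-stroke mortality. A steep gradient would make arm-to-arm
   differences in age *dispersion* (SDs range 13.4–17.4 y across arms)
   drive conditional life expectancy, whereas with identical event hazards
   across arms the comparison is meant to be carried by the Day-90 mRS
   mix. With the flatter gradient, conditional-on-survival life expectancy
   is nearly equal across arms and the mRS-6 fraction and functional mix
   at Day 90 do the work.

Because every arm shares the same hazards (a conservative choice — no
carry-over treatment effect on long-term event rates is assumed), all
between-arm differences in outcomes arise from the Day-90 state mix and
demographics.

## Economics

Costs (AUD 2018; 1 AUD = 0.75 USD is applied only at reporting time) and
utilities attach to the trace as:

* a lump **index acute cost** at t = 0 by treatment arm (EVT arms include
  the procedure);
* **annual management cost** by current mRS, plus a post-MI annual
  increment, integrated between events;
* lump **event costs** at event times (recurrent-stroke admission by drawn
  severity; MI hospitalization);
* **utility** by current mRS integrated between events, minus a temporary
  decrement (default 0.125 for 1 year, clipped at death/horizon) after any
  non-fatal CVD event. A new event resets the decrement window rather than
  stacking — overlapping events are rare at these hazards and stacking
  would double-count the acute disutility.

Discounting is continuous at an annual-equivalent 3% — the natural
convention for a continuous-time engine; it differs from annual-cycle
discounting by under 1.5% at 3% and is applied identically to costs and
QALYs, so incremental comparisons are insensitive to the convention. All
cost and utility values are flagged `assumed` in the parameter files: the
source study's supplementary tables are not public, so the packaged
schedule is a literature-class default chosen to be monotone in mRS
(worse function ⇒ higher management cost, lower utility). The qualitative
base-case findings survive any monotone re-specification of these
schedules; absolute totals of course do not.

## Incremental analysis and sensitivity

For strategy A vs comparator B, `incremental()` reports ΔC, ΔE, the ICER
(ΔC/ΔE when ΔE ≠ 0), net monetary benefit `NMB = WTP·ΔE − ΔC`, and a
classification: `dominant` (ΔC < 0, ΔE > 0), `dominated` (ΔC > 0, ΔE < 0),
otherwise cost-effective by the sign of the NMB. A configurable
**mortality override** (default on) reclassifies a nominally
cost-effective strategy as `mortality_dominated` when it causes more
deaths per patient than its comparator — the situation that arises for
criteria-negative EVT against criteria-negative medical care, where the
ICER falls below the threshold yet survival is worse.

One-way deterministic sensitivity re-runs the pipeline at each parameter's
bounds with the shared base seed and reports spreads for a tornado
diagram. The tornado outcome is the NMB at the base WTP rather than the
ICER, because the ICER changes sign (and meaning) when ΔE crosses zero in
exactly the comparisons of interest. Default ranges cover the time
horizon (5–25 y), discount rate (0–5%), fatal-recurrence probability
(0.10–0.30) and acute recurrent-stroke costs (±50%), among others.

The probabilistic sensitivity analysis draws parameters independently —
gamma for costs, beta for utilities and probabilities, log-normal for
hazards, with coefficients of variation of 10–20% declared in
`psa_manifest.csv`. Independence is an explicit modelling assumption.
Utility draws are sorted decreasing across mRS so every draw respects the
schedule's monotonicity (rank-preserving, standard practice). Within a
draw both arms are simulated with a shared patient-level seed, and the
same engine seed is reused across draws: differences across draws are then
purely parametric, and a zero-variance manifest collapses the incremental
plane to a single point. The acceptability curve reports, per WTP value,
the fraction of draws with positive NMB.

## Problem sizes and numerical choices

The base-case scripts use 20,000 patients per arm (the package default is
50,000); arm-level means stabilise well below that, and the script states
its `n` in the output. The PSA uses 1,000 draws × 2,000 patients per arm
with common random numbers, which holds the Monte-Carlo component of the
draw-to-draw variation far below the parametric component. Oracle-backed
tolerances: the engine's survival curve must match the mortality table's
closed-form survival within 1% sup-norm at n = 10⁵; discounting matches
quadrature to 1e-9; the Gompertz sampler must be within KS distance 0.01
of the exponential at shape 1e-6; both accrual routes agree to 1e-9.
Degenerate inputs are defined, not errors: zero hazard rates disable a
process, a zero-variance PSA manifest reproduces the base case, caliper 0
matches only equal scores, and an empty arm summary reports n = 0.

## Known limitations

* Marginal (uncorrelated) registry generation; no imaging, only generated
  volumes.
* Identical long-term hazards across arms: any true carry-over benefit of
  reperfusion on late event rates is ignored (conservative for EVT).
* Recurrent-stroke severity affects costs/utilities but not subsequent
  hazards; no hazard escalation with event count.
* The packaged cost, utility, hazard and mortality values are assumptions
  standing in for non-public supplementary tables; absolute costs and
  QALYs should not be quoted against the source study's totals — the
  worked examples on the packaged reference table exist precisely to keep
  that arithmetic separate from the simulation.
* Single healthcare-system perspective and currency basis; no
  inflation/indexation machinery.

```{r, eval = FALSE}
# end-to-end, at reduced size
params <- default_parameters()
bc <- run_base_case(params, n_patients = 5000, seed = 1)
bc$incrementals
```
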