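# Perfusion-imaging eligibility per the published late-window trial rules.
# Boundary conventions: "large core" is strictly core > 70 ml; all core
# caps are strict less-than (a core of exactly 21 ml fails the >=80-years
# clinical-core mismatch band).

#' Classify a patient against the DEFUSE 3 imaging criteria
#'
#' Eligible iff core volume is under the core cap AND the perfusion/core
#' mismatch ratio meets the floor AND the mismatch volume (perfusion - core)
#' meets the floor. With a zero perfusion lesion the ratio is undefined; the
#' patient is classified ineligible with a warning (no division occurs).
#'
#' @param records Data frame with `core_volume` and
#'   `perfusion_lesion_volume` (a single patient row or many).
#' @param criteria Criteria configuration (`params$criteria`); thresholds
#'   under `$defuse3`.
#' @return Logical vector.
#' @export
classify_defuse3 <- function(records, criteria) {
  th <- criteria$defuse3
  core <- records$core_volume
  perf <- records$perfusion_lesion_volume
  if (any(core < 0 | perf < 0)) stop("volumes must be non-negative")
  zero <- perf == 0
  if (any(zero)) {
    warning("perfusion lesion volume 0 for ", sum(zero),
            " record(s): mismatch ratio undefined, classified ineligible")
  }
  ratio_ok <- !zero & (perf >= th$mismatch_ratio_min * core)
  core_ok <- core < th$core_max_ml
  vol_ok <- (perf - core) >= th$mismatch_volume_min_ml
  core_ok & ratio_ok & vol_ok
}

#' Classify a patient against the DAWN clinical-core mismatch criteria
#'
#' Age-banded table: at `age >= 80`, NIHSS >= 10 with core under the elderly
#' cap; under 80, either NIHSS >= 10 with core under the standard cap, or
#' NIHSS >= severe floor with core under the extended cap. NIHSS below the
#' configured minimum is simply ineligible (not an error). Core caps are
#' strict less-than.
#'
#' @param records Data frame with `age`, `nihss`, `core_volume`.
#' @param criteria Criteria configuration; thresholds under `$dawn`.
#' @return Logical vector.
#' @export
classify_dawn <- function(records, criteria) {
  th <- criteria$dawn
  age <- records$age; nihss <- records$nihss; core <- records$core_volume
  if (any(is.na(age) | is.na(nihss))) stop("age and nihss must be populated")
  elderly <- age >= th$age_elderly
  eligible <- ifelse(
    elderly,
    nihss >= th$nihss_min & core < th$elderly_core_max_ml,
    (nihss >= th$nihss_min & core < th$young_core_max_ml) |
      (nihss >= th$young_severe_nihss_min & core < th$young_severe_core_max_ml)
  )
  eligible & nihss >= th$nihss_min
}

#' Eligibility flags for every record
#'
#' @param records Registry data frame.
#' @param criteria Criteria configuration.
#' @return Data frame: `defuse3_positive`, `dawn_positive`,
#'   `target_mismatch` (the DEFUSE 3 mismatch test alone, without the core
#'   cap), `large_core` (core strictly over the large-core threshold).
#' @export
eligibility_flags <- function(records, criteria) {
  perf <- records$perfusion_lesion_volume
  core <- records$core_volume
  th <- criteria$defuse3
  mismatch <- perf > 0 & (perf >= th$mismatch_ratio_min * core) &
    (perf - core) >= th$mismatch_volume_min_ml
  data.frame(
    id = records$id,
    defuse3_positive = suppressWarnings(classify_defuse3(records, criteria)),
    dawn_positive = classify_dawn(records, criteria),
    target_mismatch = mismatch,
    large_core = core > criteria$large_core_ml,
    stringsAsFactors = FALSE
  )
}
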