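# Shared fixtures: the packaged parameter set (loaded once) and helpers to
# build modified copies for degenerate scenarios.

tp <- evtdes::default_parameters(quiet = TRUE)

# all event and death processes switched off: the only possible transition
# is reaching the horizon
null_params <- function(p = tp) {
  p$hazards$recurrent_stroke$rate <- 0
  p$hazards$mi$rate <- 0
  p$hazards$cvd_death$rate <- 0
  for (cc in c("noncvd_male", "noncvd_female", "cvd_male", "cvd_female")) {
    p$mortality[[cc]] <- rep(0, nrow(p$mortality))
  }
  p
}

# background (non-CVD) mortality only
background_only_params <- function(p = tp) {
  p$hazards$recurrent_stroke$rate <- 0
  p$hazards$mi$rate <- 0
  p$hazards$cvd_death$rate <- 0
  for (cc in c("cvd_male", "cvd_female")) {
    p$mortality[[cc]] <- rep(0, nrow(p$mortality))
  }
  p
}

# a minimal cohort data frame for arm simulation
make_cohort <- function(n, mrs = 3L, age = 70, sex = "female",
                        treatment = "none") {
  data.frame(id = paste0("p", seq_len(n)), age = rep_len(age, n),
              sex = rep_len(sex, n), mrs_90d = rep_len(as.integer(mrs), n),
              treatment = rep_len(treatment, n), stringsAsFactors = FALSE)
}

# hand-built event trace for the economics oracle tests
make_trace <- function(initial_mrs, events, death_time = NA_real_) {
  structure(list(id = 1L, initial_mrs = as.integer(initial_mrs),
                 events = events, death_time = death_time),
            class = "event_trace")
}

# flat mortality table with constant hazards
flat_mortality <- function(h_noncvd = 0.01, h_cvd = 0, ages = 18:100) {
  data.frame(age = ages,
             noncvd_male = rep(h_noncvd, length(ages)),
             noncvd_female = rep(h_noncvd, length(ages)),
             cvd_male = rep(h_cvd, length(ages)),
             cvd_female = rep(h_cvd, length(ages)))
}

# editable copy of the packaged configuration directory
copy_config <- function() {
  src <- dirname(evtdes::default_config_path())
  dst <- file.path(tempfile("cfg"), "extdata")
  dir.create(dst, recursive = TRUE)
  file.copy(list.files(src, full.names = TRUE), dst)
  file.path(dst, "config.yaml")
}
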