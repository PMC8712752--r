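#' Load and validate the full model parameter set
#'
#' Reads the master YAML configuration and every parameter table it
#' references (cohort spec, eligibility criteria, hazards, mortality table,
#' fatality rules, costs, utilities, PSA manifest, DSA ranges), validates
#' each against its schema, and returns a single `evtdes_params` list used by
#' all downstream stages. Rows flagged `assumed` in the tables are surfaced
#' in a startup message so users can see which inputs are literature-class
#' defaults rather than study-sourced values.
#'
#' @param config_path Path to the YAML configuration. Defaults to the
#'   packaged configuration under `extdata`.
#' @param quiet Suppress the assumed-defaults message.
#' @return A list of class `evtdes_params` with elements `cohort_spec`,
#'   `criteria`, `hazards`, `mortality`, `fatality`, `costs`, `utilities`,
#'   `severity_recurrent`, `psa_manifest`, `dsa_ranges`, `discount_rate`,
#'   `horizon_years`, `n_patients`, `wtp`, `aud_per_usd`,
#'   `mortality_dominance_override`.
#' @export
load_parameters <- function(config_path = default_config_path(), quiet = FALSE) {
  if (!file.exists(config_path)) {
    stop("configuration file not found: ", config_path)
  }
  cfg <- yaml::read_yaml(config_path)
  dir <- dirname(config_path)
  path_of <- function(key) {
    p <- cfg$files[[key]]
    if (is.null(p)) stop("config is missing files entry '", key, "'")
    if (!file.path_is_absolute(p)) p <- file.path(dir, p)
    if (!file.exists(p)) stop("parameter file for '", key, "' not found: ", p)
    p
  }

  cohort_spec <- load_cohort_spec(path_of("cohort_spec"))
  criteria    <- load_criteria(path_of("criteria"))
  hazards_raw <- read.csv(path_of("hazards"), stringsAsFactors = FALSE)
  mortality   <- load_mortality_table(path_of("mortality"))
  fatality_raw <- read.csv(path_of("fatality"), stringsAsFactors = FALSE)
  costs_raw    <- read.csv(path_of("costs"), stringsAsFactors = FALSE)
  util_raw     <- read.csv(path_of("utilities"), stringsAsFactors = FALSE)
  psa_manifest <- read.csv(path_of("psa_manifest"), stringsAsFactors = FALSE)
  dsa_ranges   <- read.csv(path_of("dsa_ranges"), stringsAsFactors = FALSE)

  fat <- setNames(fatality_raw$value, fatality_raw$parameter)
  for (p in c("p_fatal_recurrent_stroke", "p_fatal_mi", "mi_fraction")) {
    v <- fat[[p]]
    if (is.null(v) || is.na(v)) stop("fatality table missing parameter '", p, "'")
    if (v < 0 || v > 1) {
      stop("fatality table: probability out of [0,1] for '", p, "' (", v, ")")
    }
  }

  hazards <- build_hazards(hazards_raw, mi_fraction = fat[["mi_fraction"]])
  costs <- build_cost_schedule(costs_raw)
  utilities <- build_utility_schedule(util_raw)

  sev <- unlist(cfg$severity_recurrent)
  if (length(sev) != 6 || any(sev < 0) || abs(sum(sev) - 1) > 1e-9) {
    stop("severity_recurrent must be 6 non-negative probabilities summing to 1")
  }

  an <- cfg$analysis
  if (is.null(an$discount_rate) || an$discount_rate < 0) {
    stop("analysis.discount_rate must be >= 0")
  }
  if (is.null(an$horizon_years) || an$horizon_years <= 0) {
    stop("analysis.horizon_years must be > 0")
  }

  params <- structure(list(
    cohort_spec = cohort_spec,
    criteria = criteria,
    hazards = hazards,
    mortality = mortality,
    fatality = list(
      p_fatal_recurrent_stroke = unname(fat[["p_fatal_recurrent_stroke"]]),
      p_fatal_mi = unname(fat[["p_fatal_mi"]]),
      mi_fraction = unname(fat[["mi_fraction"]])
    ),
    costs = costs,
    utilities = utilities,
    severity_recurrent = unname(sev),
    psa_manifest = psa_manifest,
    dsa_ranges = dsa_ranges,
    discount_rate = an$discount_rate,
    horizon_years = an$horizon_years,
    n_patients = an$n_patients,
    wtp = an$wtp,
    aud_per_usd = an$aud_per_usd,
    mortality_dominance_override = isTRUE(an$mortality_dominance_override)
  ), class = "evtdes_params")

  assumed <- c(
    sprintf("hazards: %s", hazards_raw$event[isTRUE_vec(hazards_raw$assumed)]),
    sprintf("fatality: %s", fatality_raw$parameter[isTRUE_vec(fatality_raw$assumed)]),
    sprintf("costs: %s[%s]", costs_raw$item[isTRUE_vec(costs_raw$assumed)],
            costs_raw$state[isTRUE_vec(costs_raw$assumed)]),
    sprintf("utilities: %s[%s]", util_raw$item[isTRUE_vec(util_raw$assumed)],
            util_raw$state[isTRUE_vec(util_raw$assumed)])
  )
  attr(params, "assumed_defaults") <- assumed
  if (!quiet && length(assumed)) {
    message(length(assumed),
            " parameter rows are assumed defaults (not study-sourced); ",
            "see attr(params, 'assumed_defaults')")
  }
  params
}

#' @export
print.evtdes_params <- function(x, ...) {
  cat("<evtdes_params>\n")
  cat("  horizon:", x$horizon_years, "y  discount:", x$discount_rate,
      " WTP:", x$wtp, "AUD/QALY\n")
  cat("  arms:", paste(names(x$cohort_spec$arms), collapse = ", "), "\n")
  cat("  assumed-default rows:", length(attr(x, "assumed_defaults")), "\n")
  invisible(x)
}

#' Path to the packaged default configuration
#' @return File path of the YAML configuration shipped with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "config.yaml", package = "evtdes", mustWork = TRUE)
}

#' Packaged default parameter set
#'
#' Convenience wrapper: [load_parameters()] on the packaged configuration.
#' @param quiet Suppress the assumed-defaults message (default TRUE here).
#' @return An `evtdes_params` list.
#' @export
default_parameters <- function(quiet = TRUE) {
  load_parameters(default_config_path(), quiet = quiet)
}

# ---- internal builders -----------------------------------------------------

isTRUE_vec <- function(x) {
  if (is.logical(x)) !is.na(x) & x else toupper(trimws(as.character(x))) == "TRUE"
}

file.path_is_absolute <- function(p) {
  grepl("^(/|[A-Za-z]:)", p)
}

load_cohort_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$arms) || !length(spec$arms)) stop("cohort spec has no arms")
  for (arm in names(spec$arms)) {
    a <- spec$arms[[arm]]
    if (is.null(a$size) || a$size < 1) {
      stop("cohort spec arm '", arm, "': size must be >= 1")
    }
    mrs <- unlist(a$mrs_counts)
    if (length(mrs) != 7 || any(mrs < 0) || sum(mrs) <= 0) {
      stop("cohort spec arm '", arm, "': mrs_counts must be 7 non-negative counts")
    }
    tp <- unlist(a$treatment_probs)
    if (abs(sum(tp) - 1) > 1e-9) {
      stop("cohort spec arm '", arm,
           "': treatment_probs must sum to 1 (got ", sum(tp), ")")
    }
    if (a$male_prop < 0 || a$male_prop > 1) {
      stop("cohort spec arm '", arm, "': male_prop outside [0,1]")
    }
  }
  spec
}

load_criteria <- function(path) {
  yaml::read_yaml(path)
}

#' Load and validate a mortality table
#'
#' Age-indexed annual hazards of non-CVD and CVD death per sex. Ages must be
#' consecutive integers; hazards must be non-negative. Lookups beyond the
#' last tabulated age use the last row (documented extrapolation rule); a
#' notice is emitted when the table stops before age 100.
#'
#' @param path CSV with columns `age`, `noncvd_male`, `noncvd_female`,
#'   `cvd_male`, `cvd_female`.
#' @return A validated data.frame with attribute `age_range`.
#' @export
load_mortality_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "noncvd_male", "noncvd_female", "cvd_male", "cvd_female")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("mortality table missing columns: ", paste(miss, collapse = ", "))
  if (any(diff(tab$age) != 1)) stop("mortality table ages must be consecutive integers")
  for (col in need[-1]) {
    if (any(tab[[col]] < 0 | is.na(tab[[col]]))) {
      stop("mortality table: negative or missing hazard in column '", col, "'")
    }
  }
  if (max(tab$age) < 100) {
    message("mortality table ends at age ", max(tab$age),
            "; hazards beyond use last-value extrapolation")
  }
  attr(tab, "age_range") <- range(tab$age)
  tab
}

build_hazards <- function(raw, mi_fraction) {
  get_row <- function(ev) raw[raw$event == ev, , drop = FALSE]
  rs <- get_row("recurrent_stroke")
  if (!nrow(rs)) stop("hazards table missing event 'recurrent_stroke'")
  if (rs$rate <= 0) stop("hazards table: recurrent_stroke rate must be > 0")
  comb <- get_row("mi_vascular_combined")
  if (!nrow(comb)) stop("hazards table missing event 'mi_vascular_combined'")
  combined_rate <- calibrate_exponential(comb$risk, comb$risk_horizon_years)
  alt <- get_row("recurrent_stroke_alt")
  list(
    recurrent_stroke = hazard_spec(rs$distribution, rate = rs$rate,
                                   shape = if (!is.na(rs$shape)) rs$shape else NULL,
                                   event = "recurrent_stroke"),
    recurrent_stroke_alt = if (nrow(alt)) {
      hazard_spec(alt$distribution, rate = alt$rate, shape = alt$shape,
                  event = "recurrent_stroke")
    },
    mi = hazard_spec("exponential", rate = combined_rate * mi_fraction,
                     event = "mi"),
    cvd_death = hazard_spec("exponential",
                            rate = combined_rate * (1 - mi_fraction),
                            event = "cvd_death"),
    combined_risk = comb$risk,
    combined_risk_horizon = comb$risk_horizon_years,
    combined_rate = combined_rate
  )
}

build_cost_schedule <- function(raw) {
  val <- function(item, state = NULL) {
    rows <- raw[raw$item == item & (if (is.null(state)) TRUE else raw$state %in% state), ]
    if (!nrow(rows)) stop("cost table missing item '", item, "'")
    rows
  }
  idx <- val("index_acute")
  index <- setNames(idx$value, idx$state)
  ars <- val("acute_recurrent_stroke")
  ars <- ars[order(as.integer(ars$state)), ]
  mgmt <- val("annual_management")
  mgmt <- mgmt[order(as.integer(mgmt$state)), ]
  sched <- list(
    index_acute = index,
    acute_recurrent_stroke = ars$value,     # mRS severity 0..6
    mi_hospitalization = val("mi_hospitalization")$value,
    annual_management = mgmt$value,         # mRS 0..6
    post_mi_annual = val("post_mi_annual")$value
  )
  stopifnot(length(sched$acute_recurrent_stroke) == 7,
            length(sched$annual_management) == 7)
  if (any(unlist(sched) < 0)) stop("cost table: all costs must be >= 0")
  sched
}

build_utility_schedule <- function(raw) {
  u <- raw[raw$item == "utility", ]
  u <- u[order(as.integer(u$state)), ]
  if (nrow(u) != 7) stop("utility table must have states 0..6")
  vals <- u$value
  if (vals[7] != 0) stop("utility for mRS 6 (death) must be 0")
  if (any(vals[1:6] > 1) || any(vals[1:6] < -0.2)) {
    stop("utilities for mRS 0-5 must lie in [-0.2, 1]")
  }
  if (any(diff(vals[1:6]) > 1e-12)) {
    stop("utilities must be monotone non-increasing in mRS")
  }
  dec <- raw[raw$item == "event_decrement", "value"]
  dur <- raw[raw$item == "decrement_duration", "value"]
  if (!length(dec) || !length(dur)) stop("utility table missing decrement rows")
  if (dur < 0 || dec < 0) stop("decrement and duration must be >= 0")
  list(by_mrs = vals, event_decrement = dec, decrement_duration = dur)
}
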