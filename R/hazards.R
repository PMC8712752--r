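#' Construct a time-to-event hazard specification
#'
#' @param distribution `"exponential"` or `"gompertz"`.
#' @param rate Exponential rate per year, or the Gompertz baseline hazard
#'   `b` (per year) when `distribution = "gompertz"`.
#' @param shape Gompertz shape `a` per year (any real; negative shapes give a
#'   defective distribution where the event may never occur). Ignored for the
#'   exponential.
#' @param event Event label, e.g. `"recurrent_stroke"` or `"mi"`.
#' @return A list of class `hazard_spec`.
#' @export
hazard_spec <- function(distribution = c("exponential", "gompertz"),
                        rate, shape = NULL, event = "event") {
  distribution <- match.arg(distribution)
  # rate 0 is allowed and disables the process (the event never occurs)
  if (rate < 0) stop("hazard rate/baseline must be >= 0")
  if (distribution == "gompertz" && is.null(shape)) {
    stop("gompertz hazard requires a shape")
  }
  structure(list(distribution = distribution, rate = rate,
                 shape = shape, event = event),
            class = "hazard_spec")
}

#' Calibrate an exponential rate from a cumulative risk
#'
#' Solves `1 - exp(-rate * horizon) = cumulative_risk` for the constant
#' per-year hazard, e.g. the combined MI/vascular-death process whose 5-year
#' cumulative incidence is 17.4%.
#'
#' @param cumulative_risk Probability in (0, 1).
#' @param horizon_years Horizon over which the risk accumulates, > 0.
#' @return Rate per year.
#' @examples
#' calibrate_exponential(0.174, 5)  # ~0.03823 per year
#' @export
calibrate_exponential <- function(cumulative_risk, horizon_years) {
  if (!is.finite(cumulative_risk) || cumulative_risk <= 0 || cumulative_risk >= 1) {
    stop("cumulative_risk must lie strictly inside (0, 1)")
  }
  if (horizon_years <= 0) stop("horizon_years must be > 0")
  -log(1 - cumulative_risk) / horizon_years
}

#' Sample event times by inverse transform
#'
#' Exponential: `-log(U)/rate`. Gompertz with shape `a` and baseline `b`:
#' `(1/a) * log(1 - (a/b) * log(U))`. For `a < 0` the distribution is
#' defective; draws falling in the defective mass return `Inf` (the event
#' never occurs).
#'
#' @param spec A [hazard_spec()].
#' @param n Number of draws.
#' @return Numeric vector of times in years, each > 0 (or `Inf`).
#' @export
sample_event_time <- function(spec, n = 1) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (spec$rate == 0) return(rep(Inf, n))
  u <- runif(n)
  if (spec$distribution == "exponential") {
    return(-log(u) / spec$rate)
  }
  a <- spec$shape; b <- spec$rate
  if (abs(a) < 1e-12) return(-log(u) / b)
  arg <- 1 - (a / b) * log(u)
  # a < 0: survival plateaus at exp(b/a); draws below never experience the event
  t <- rep(Inf, n)
  pos <- arg > 0
  t[pos] <- log(arg[pos]) / a
  t
}

#' Sample time to death from an age-indexed mortality table
#'
#' Piecewise-constant-hazard (piecewise-exponential) sampling: the annual
#' hazard is constant within each integer year of age, read from the table
#' column for the requested cause and sex, with last-value extrapolation
#' beyond the tabulated range. With a flat table this reduces exactly to an
#' exponential draw.
#'
#' @param current_age Numeric vector of current ages in years (fractional ok).
#' @param sex Character vector, `"male"`/`"female"`, recycled.
#' @param table Mortality table from [load_mortality_table()].
#' @param cause `"noncvd"` or `"cvd"`.
#' @return Vector of times to death in years (possibly `Inf` when the
#'   hazard is identically zero from the current age on).
#' @export
sample_background_death <- function(current_age, sex, table, cause = "noncvd") {
  n <- length(current_age)
  sex <- rep_len(sex, n)
  hm <- table[[paste0(cause, "_male")]]
  hf <- table[[paste0(cause, "_female")]]
  ages <- table$age
  a_min <- ages[1]; a_max <- ages[length(ages)]

  idx_of <- function(a) pmin(pmax(floor(a), a_min), a_max) - a_min + 1L

  E <- rexp(n)                       # unit-exponential total hazard target
  t_out <- numeric(n)
  rem <- E
  cur <- current_age
  male <- sex == "male"
  act <- seq_len(n)
  # first (possibly partial) year, then whole years
  width <- 1 - (cur - floor(cur))
  width[width == 0] <- 1
  while (length(act)) {
    # at or beyond the last tabulated age the hazard is constant
    # (last-value extrapolation): finish those draws in closed form
    beyond <- act[cur[act] >= a_max]
    if (length(beyond)) {
      h_last <- ifelse(male[beyond], hm[length(hm)], hf[length(hf)])
      t_out[beyond] <- t_out[beyond] +
        ifelse(h_last > 0, rem[beyond] / h_last, Inf)
      act <- setdiff(act, beyond)
      if (!length(act)) break
    }
    i <- idx_of(cur[act])
    h <- ifelse(male[act], hm[i], hf[i])
    H <- h * width[act]
    fin <- h > 0 & rem[act] <= H
    if (any(fin)) {
      j <- act[fin]
      t_out[j] <- t_out[j] + rem[j] / h[fin]
    }
    keep <- !fin
    j <- act[keep]
    rem[j] <- rem[j] - H[keep]
    t_out[j] <- t_out[j] + width[j]
    cur[j] <- floor(cur[j] + width[j] + 1e-9)
    width[j] <- 1
    act <- j
  }
  t_out
}

#' Closed-form survival under a mortality table
#'
#' Product-form survival implied by piecewise-constant annual hazards:
#' `S(t) = exp(-sum of hazard x exposure over the age years crossed)`.
#' Used as the analytic oracle against which the sampler and the
#' discrete-event engine are checked.
#'
#' @param t Times in years (vector).
#' @param start_age Age at time 0.
#' @param sex `"male"` or `"female"`.
#' @param table Mortality table.
#' @param cause `"noncvd"` or `"cvd"`, or `"both"` to combine.
#' @return Survival probabilities at `t`.
#' @export
mortality_survival <- function(t, start_age, sex, table, cause = "noncvd") {
  cols <- if (cause == "both") c("noncvd", "cvd") else cause
  hz <- rep(0, length(table$age))
  for (cc in cols) hz <- hz + table[[paste0(cc, "_", sex)]]
  ages <- table$age
  a_min <- ages[1]; a_max <- ages[length(ages)]
  sapply(t, function(tt) {
    if (tt <= 0) return(1)
    H <- 0; cur <- start_age; remain <- tt
    while (remain > 1e-12) {
      i <- min(max(floor(cur), a_min), a_max) - a_min + 1
      w <- min(1 - (cur - floor(cur)), remain)
      if (w == 0) w <- min(1, remain)
      H <- H + hz[i] * w
      cur <- cur + w
      remain <- remain - w
    }
    exp(-H)
  })
}
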