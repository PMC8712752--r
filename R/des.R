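# Discrete-event engine. Patients start at Day 90 (t = 0) in an mRS state
# 0..6 and experience competing risks: recurrent stroke, MI, CVD death and
# non-CVD death, with clocks re-sampled after each non-fatal event
# (memoryless renewal; the age-indexed background hazards are re-sampled
# conditionally on current age, which is exact for piecewise-constant
# hazards). Simultaneous candidate times are broken by a fixed priority:
# non-CVD death, CVD death, recurrent stroke, MI, horizon.

disc_flow_vec <- function(rate, t1, t2) {
  if (rate == 0) return(t2 - t1)
  (exp(-rate * t1) - exp(-rate * t2)) / rate
}

rexp_or_inf <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else rexp(n, rate)
}

sample_tte <- function(spec, n) {
  if (is.null(spec) || spec$rate <= 0) return(rep(Inf, n))
  sample_event_time(spec, n)
}

# Core vectorised simulation of one cohort of patients. Economic accrual is
# done inline with closed-form discounting; the independent per-trace
# integrator accrue_trace() reproduces these totals (tested to 1e-9).
sim_cohort_engine <- function(initial_mrs, age, sex, params,
                              horizon = params$horizon_years,
                              keep_trace = FALSE,
                              hazard_rs = params$hazards$recurrent_stroke) {
  n <- length(initial_mrs)
  r <- params$discount_rate
  costs <- params$costs
  util <- params$utilities
  mort <- params$mortality
  rate_mi <- params$hazards$mi$rate
  pf_rs <- params$fatality$p_fatal_recurrent_stroke
  pf_mi <- params$fatality$p_fatal_mi
  sev_cum <- cumsum(params$severity_recurrent)
  dec <- util$event_decrement
  dur <- util$decrement_duration

  t_now <- numeric(n)
  mrs <- as.integer(initial_mrs)
  cost <- numeric(n)
  qaly <- numeric(n); ly_d <- numeric(n); ly <- numeric(n)
  n_rs <- integer(n); n_mi <- integer(n)
  death_time <- rep(NA_real_, n)
  dec_until <- numeric(n)

  lg_pid <- integer(0); lg_t <- numeric(0); lg_k <- character(0)
  lg_m <- integer(0); lg_s <- integer(0)
  log_ev <- function(pid, tt, kk, mm, ss = rep(NA_integer_, length(pid))) {
    lg_pid <<- c(lg_pid, pid); lg_t <<- c(lg_t, tt)
    lg_k <<- c(lg_k, kk); lg_m <<- c(lg_m, mm); lg_s <<- c(lg_s, ss)
  }

  dead0 <- mrs == 6L
  if (any(dead0)) {
    death_time[dead0] <- 0
    if (keep_trace) log_ev(which(dead0), rep(0, sum(dead0)),
                           rep("cvd_death", sum(dead0)), rep(6L, sum(dead0)))
  }
  act <- which(!dead0)

  kind_names <- c("noncvd_death", "cvd_death", "recurrent_stroke", "mi", "horizon_end")

  while (length(act)) {
    m <- length(act)
    t_rs <- sample_tte(hazard_rs, m)
    t_mi <- rexp_or_inf(m, rate_mi)
    cur_age <- age[act] + t_now[act]
    t_cv <- sample_background_death(cur_age, sex[act], mort, "cvd")
    t_nc <- sample_background_death(cur_age, sex[act], mort, "noncvd")
    t_hor <- horizon - t_now[act]
    cand <- cbind(t_nc, t_cv, t_rs, t_mi, t_hor)
    ki <- max.col(-cand, ties.method = "first")
    dt <- cand[cbind(seq_len(m), ki)]
    t_next <- t_now[act] + dt

    # accrual over [t_now, t_next) in the current state
    ann <- costs$annual_management[mrs[act] + 1L] +
      costs$post_mi_annual * (n_mi[act] > 0L)
    f <- disc_flow_vec(r, t_now[act], t_next)
    cost[act] <- cost[act] + ann * f
    qaly[act] <- qaly[act] + util$by_mrs[mrs[act] + 1L] * f
    ov_end <- pmin(dec_until[act], t_next)
    ov <- which(ov_end > t_now[act])
    if (length(ov)) {
      qaly[act[ov]] <- qaly[act[ov]] -
        dec * disc_flow_vec(r, t_now[act][ov], ov_end[ov])
    }
    ly_d[act] <- ly_d[act] + f
    ly[act] <- ly[act] + dt

    u_fatal <- runif(m)
    u_sev <- runif(m)
    new_mrs <- mrs[act]
    died <- ki <= 2L
    ev_mrs <- ifelse(died, 6L, new_mrs)

    is_rs <- ki == 3L
    if (any(is_rs)) {
      rs_fatal <- is_rs & u_fatal < pf_rs
      sev <- findInterval(u_sev, sev_cum)        # 0..5
      sev[rs_fatal] <- 6L
      cost[act[is_rs]] <- cost[act[is_rs]] +
        discounted_point(costs$acute_recurrent_stroke[sev[is_rs] + 1L], r,
                         t_next[is_rs])
      nf <- is_rs & !rs_fatal
      new_mrs[nf] <- pmax(new_mrs[nf], sev[nf])
      dec_until[act[nf]] <- t_next[nf] + dur
      died <- died | rs_fatal
      ev_mrs[nf] <- new_mrs[nf]
      ev_mrs[rs_fatal] <- 6L
      n_rs[act[is_rs]] <- n_rs[act[is_rs]] + 1L
    }
    is_mi <- ki == 4L
    if (any(is_mi)) {
      mi_fatal <- is_mi & u_fatal < pf_mi
      cost[act[is_mi]] <- cost[act[is_mi]] +
        discounted_point(costs$mi_hospitalization, r, t_next[is_mi])
      nf <- is_mi & !mi_fatal
      dec_until[act[nf]] <- t_next[nf] + dur
      died <- died | mi_fatal
      ev_mrs[mi_fatal] <- 6L
      n_mi[act[is_mi]] <- n_mi[act[is_mi]] + 1L
    }
    is_hor <- ki == 5L

    if (any(died)) death_time[act[died]] <- t_next[died]
    if (keep_trace) {
      sev_log <- rep(NA_integer_, m)
      if (any(is_rs)) sev_log[is_rs] <- as.integer(sev[is_rs])
      log_ev(act, t_next, kind_names[ki], ev_mrs, sev_log)
    }

    mrs[act] <- ifelse(died, 6L, new_mrs)
    t_now[act] <- t_next
    act <- act[!(died | is_hor)]
  }

  out <- list(cost = cost, qaly = qaly, ly_discounted = ly_d, ly = ly,
              n_stroke = n_rs, n_mi = n_mi, death_time = death_time)
  if (keep_trace) {
    ord <- order(lg_pid, lg_t)
    out$event_log <- data.frame(patient = lg_pid[ord], time = lg_t[ord],
                                kind = lg_k[ord], mrs_after = lg_m[ord],
                                severity = lg_s[ord],
                                stringsAsFactors = FALSE)
  }
  out
}

#' Simulate one patient's post-Day-90 life course
#'
#' Competing-risk loop over recurrent stroke, MI, CVD death and non-CVD
#' death; non-fatal MI/stroke events apply Bernoulli case-fatality rules,
#' survivors re-enter the loop with clocks re-sampled and age advanced. An
#' initial mRS of 6 yields an immediate death at t = 0 (index costs only).
#'
#' @param initial_mrs Integer 0..6, the Day-90 modified Rankin Scale state.
#' @param age Age in years at Day 90.
#' @param sex `"male"` or `"female"`.
#' @param params Parameter set from [load_parameters()].
#' @param seed Integer seed (the trace is reproducible given the seed).
#' @param horizon Years simulated from Day 90.
#' @param hazard_rs Recurrent-stroke hazard; defaults to the packaged
#'   exponential, pass `params$hazards$recurrent_stroke_alt` for the
#'   Gompertz sensitivity process.
#' @return An object of class `event_trace`: `initial_mrs`, ordered `events`
#'   data frame (`time`, `kind`, `mrs_after`), `death_time` (`NA` when alive
#'   at the horizon).
#' @export
simulate_patient <- function(initial_mrs, age, sex, params, seed = 1L,
                             horizon = params$horizon_years,
                             hazard_rs = params$hazards$recurrent_stroke) {
  stopifnot(initial_mrs %in% 0:6)
  set.seed(seed)
  res <- sim_cohort_engine(initial_mrs, age, sex, params, horizon = horizon,
                           keep_trace = TRUE, hazard_rs = hazard_rs)
  ev <- res$event_log[, c("time", "kind", "mrs_after", "severity")]
  structure(list(id = 1L, initial_mrs = as.integer(initial_mrs),
                 events = ev,
                 death_time = res$death_time[1]),
            class = "event_trace")
}

#' @export
print.event_trace <- function(x, ...) {
  cat("<event_trace> initial mRS", x$initial_mrs,
      if (is.na(x$death_time)) "(alive at horizon)"
      else sprintf("(died at %.2f y)", x$death_time), "\n")
  print(x$events)
  invisible(x)
}

#' Simulate a strategy arm
#'
#' Resamples the supplied cohort records with replacement up to `n_patients`
#' (comonotone in Day-90 mRS, so that a shared seed across two arms yields
#' common random numbers), runs the discrete-event engine, and accrues
#' discounted costs, QALYs and life-years per patient.
#'
#' @param records Data frame of patient records with columns `mrs_90d`,
#'   `age`, `sex` (and optionally `treatment`).
#' @param params Parameter set.
#' @param n_patients Number of simulated patients (default from `params`).
#' @param seed Engine seed; use the same seed in two arms for common random
#'   numbers.
#' @param strategy Label for the arm.
#' @param treatment_group `"EVT"` or `"medical"`; selects the index acute
#'   cost. Inferred from `records$treatment` when absent.
#' @param horizon,hazard_rs See [simulate_patient()].
#' @param resample Resample the records with replacement up to `n_patients`
#'   (default). With `resample = FALSE` the records are simulated as-is
#'   (useful when the cohort was already generated at the target size).
#' @param keep_traces Retain the full event log (memory-heavy at large n).
#' @return An `arm_result`: per-arm means (discounted cost, QALYs, LYs,
#'   events per patient), Monte-Carlo standard errors, the per-patient
#'   vectors, and `death_time`.
#' @export
run_arm <- function(records, params, n_patients = params$n_patients,
                    seed = 1L, strategy = "arm",
                    treatment_group = NULL,
                    horizon = params$horizon_years,
                    hazard_rs = params$hazards$recurrent_stroke,
                    resample = TRUE, keep_traces = FALSE) {
  if (!nrow(records)) stop("cohort is empty")
  if (horizon <= 0) stop("horizon must be > 0")
  if (is.null(treatment_group)) {
    treatment_group <- if (any(records$treatment %in% c("EVT_only", "EVT_plus_tPA")))
      "EVT" else "medical"
  }
  set.seed(seed)
  ord <- order(records$mrs_90d, records$age)
  pool <- records[ord, , drop = FALSE]
  idx <- if (resample) {
    ceiling(runif(n_patients) * nrow(pool))
  } else {
    n_patients <- nrow(pool)
    seq_len(n_patients)
  }
  sim <- sim_cohort_engine(pool$mrs_90d[idx], pool$age[idx], pool$sex[idx],
                           params, horizon = horizon,
                           keep_trace = keep_traces, hazard_rs = hazard_rs)
  sim$cost <- sim$cost + unname(params$costs$index_acute[[treatment_group]])
  died <- !is.na(sim$death_time)
  res <- list(
    strategy = strategy,
    treatment_group = treatment_group,
    n = n_patients,
    horizon = horizon,
    discount_rate = params$discount_rate,
    seed = seed,
    mean_cost = mean(sim$cost),
    mean_qaly = mean(sim$qaly),
    mean_ly_discounted = mean(sim$ly_discounted),
    mean_ly = mean(sim$ly),
    mean_deaths = mean(died),
    mean_mi = mean(sim$n_mi),
    mean_stroke = mean(sim$n_stroke),
    se_cost = sd(sim$cost) / sqrt(n_patients),
    se_qaly = sd(sim$qaly) / sqrt(n_patients),
    death_time = sim$death_time,
    per_patient = sim[c("cost", "qaly", "ly_discounted", "ly",
                        "n_stroke", "n_mi")]
  )
  if (keep_traces) res$event_log <- sim$event_log
  structure(res, class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf(
    "<arm_result> %s (n=%d, %gy horizon)\n  cost %.0f  QALY %.3f  LY(disc) %.3f  deaths %.3f  MI %.3f  stroke %.3f\n",
    x$strategy, x$n, x$horizon, x$mean_cost, x$mean_qaly,
    x$mean_ly_discounted, x$mean_deaths, x$mean_mi, x$mean_stroke))
  invisible(x)
}

#' Rebuild per-patient event traces from a retained event log
#'
#' @param arm An `arm_result` from [run_arm()] with `keep_traces = TRUE`.
#' @param initial_mrs The per-patient initial states used (same resampling
#'   seed), or `NULL` to infer patients from the log alone.
#' @return List of `event_trace` objects indexed by patient.
#' @keywords internal
#' @export
traces_from_log <- function(arm, initial_mrs) {
  stopifnot(!is.null(arm$event_log))
  lg <- arm$event_log
  lapply(seq_along(initial_mrs), function(i) {
    ev <- lg[lg$patient == i, c("time", "kind", "mrs_after", "severity")]
    rownames(ev) <- NULL
    dt <- ev$time[ev$mrs_after == 6L | ev$kind %in% c("cvd_death", "noncvd_death")]
    structure(list(id = i, initial_mrs = as.integer(initial_mrs[i]),
                   events = ev,
                   death_time = if (length(dt)) dt[1] else NA_real_),
              class = "event_trace")
  })
}
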