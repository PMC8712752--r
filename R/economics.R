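#' Present value of a constant annual flow under continuous discounting
#'
#' `value * (exp(-r t_start) - exp(-r t_end)) / r` for `r > 0`;
#' `value * (t_end - t_start)` at `r = 0`. Discounting is continuous
#' (annual-equivalent rate), matching the continuous-time event engine.
#'
#' @param annual_value Flow per year (cost in AUD/year or utility).
#' @param rate Annual discount rate, >= 0.
#' @param t_start,t_end Interval in years, `t_start <= t_end`.
#' @return Present value at time 0. Vectorised over the time arguments.
#' @examples
#' discounted_flow(1, 0.03, 0, 25)  # 17.5806...
#' @export
discounted_flow <- function(annual_value, rate, t_start, t_end) {
  if (any(t_end < t_start)) stop("t_end must be >= t_start")
  if (rate < 0) stop("rate must be >= 0")
  if (rate == 0) return(annual_value * (t_end - t_start))
  annual_value * (exp(-rate * t_start) - exp(-rate * t_end)) / rate
}

#' Present value of a lump sum at time t
#'
#' @param value Lump sum.
#' @param rate Annual discount rate, >= 0.
#' @param t Time in years, >= 0. Vectorised.
#' @return `value * exp(-rate * t)`.
#' @export
discounted_point <- function(value, rate, t) {
  if (any(t < 0)) stop("t must be >= 0")
  value * exp(-rate * t)
}

#' Accrue discounted costs, QALYs and life-years over one event trace
#'
#' Reference per-trace integrator: walks the ordered event list of an
#' [simulate_patient()] trace, integrating the state-dependent annual
#' management cost and utility between events (with continuous discounting),
#' adding lump event costs at event times, and applying the post-CVD-event
#' utility decrement over its configured duration clipped to the next
#' death/horizon. The index acute cost enters as a lump sum at t = 0.
#'
#' This function is deliberately independent of the vectorised arm engine;
#' the two are cross-checked against each other in the test-suite.
#'
#' @param trace An `event_trace` from [simulate_patient()].
#' @param costs Cost schedule (`params$costs`).
#' @param utilities Utility schedule (`params$utilities`).
#' @param discount_rate Annual rate >= 0.
#' @param treatment_group `"EVT"` or `"medical"`: selects the index acute cost.
#' @return List with `cost`, `qaly`, `ly_discounted`, `ly` (undiscounted).
#' @export
accrue_trace <- function(trace, costs, utilities, discount_rate,
                         treatment_group = "EVT") {
  stopifnot(inherits(trace, "event_trace"))
  r <- discount_rate
  u <- utilities$by_mrs
  mgmt <- costs$annual_management
  if (any(trace$events$mrs_after < 0 | trace$events$mrs_after > 6)) {
    stop("trace contains an unknown mRS state")
  }

  cost <- unname(costs$index_acute[[treatment_group]])
  qaly <- 0; lyd <- 0; ly <- 0
  mrs <- trace$initial_mrs
  t <- 0
  n_mi <- 0L
  dec_until <- 0

  segments <- trace$events
  if (is.null(segments$severity)) segments$severity <- NA_integer_
  for (k in seq_len(nrow(segments))) {
    t2 <- segments$time[k]
    kind <- segments$kind[k]
    if (mrs != 6 && t2 > t) {
      ann <- mgmt[mrs + 1] + if (n_mi > 0) costs$post_mi_annual else 0
      cost <- cost + discounted_flow(ann, r, t, t2)
      qaly <- qaly + discounted_flow(u[mrs + 1], r, t, t2)
      ov_end <- min(dec_until, t2)
      if (ov_end > t) {
        qaly <- qaly - discounted_flow(utilities$event_decrement, r, t, ov_end)
      }
      lyd <- lyd + discounted_flow(1, r, t, t2)
      ly <- ly + (t2 - t)
    }
    if (kind == "recurrent_stroke") {
      # acute admission priced by the drawn severity of that stroke (the
      # post-event state is max(prior, severity) and may be worse)
      sev <- segments$severity[k]
      if (is.na(sev)) sev <- segments$mrs_after[k]
      cost <- cost + discounted_point(costs$acute_recurrent_stroke[sev + 1], r, t2)
      if (sev != 6) dec_until <- t2 + utilities$decrement_duration
    } else if (kind == "mi") {
      cost <- cost + discounted_point(costs$mi_hospitalization, r, t2)
      if (segments$mrs_after[k] != 6) {
        n_mi <- n_mi + 1L
        dec_until <- t2 + utilities$decrement_duration
      }
    }
    mrs <- segments$mrs_after[k]
    t <- t2
  }
  list(cost = cost, qaly = qaly, ly_discounted = lyd, ly = ly)
}
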