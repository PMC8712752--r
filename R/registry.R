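# Synthetic registry generator. Emulates the late-window (>4.5 h)
# large-vessel-occlusion cohort arm by arm from published marginals: age is
# truncated normal on the configured bounds, NIHSS a quantile-matched
# negative binomial clipped to 0..42, core and penumbra volumes
# quantile-matched log-normals (perfusion lesion = core + penumbra by
# construction, so the mismatch identity holds exactly), onset-to-imaging a
# truncated normal on (270, 1440) minutes, and the Day-90 mRS a draw from
# the arm's 7-state probability vector.

#' Fit a log-normal by quantile matching
#'
#' Matches the median and interquartile range: `meanlog = log(median)`,
#' `sdlog = log(q3/q1) / (2 * qnorm(0.75))`.
#'
#' @param median,q1,q3 Target quantiles (all > 0).
#' @return List with `meanlog`, `sdlog`.
#' @export
fit_lognormal_quantiles <- function(median, q1, q3) {
  if (min(median, q1, q3) <= 0 || q3 <= q1) {
    stop("quantiles must be positive with q1 < q3")
  }
  list(meanlog = log(median), sdlog = log(q3 / q1) / (2 * qnorm(0.75)))
}

#' Fit a negative binomial by quantile matching
#'
#' Grid search over (size, mu) minimising the squared distance between the
#' distribution's quartiles and the targets. Used for the skewed discrete
#' NIHSS marginals reported as median (IQR).
#'
#' @param median,q1,q3 Target quartiles.
#' @return List with `size`, `mu` and the achieved quartiles.
#' @export
fit_nbinom_quantiles <- function(median, q1, q3) {
  sizes <- exp(seq(log(0.5), log(200), length.out = 60))
  mus <- seq(max(1, median * 0.5), median * 1.8, length.out = 60)
  best <- NULL; best_obj <- Inf
  for (s in sizes) {
    q <- qnbinom(c(0.25, 0.5, 0.75), size = s, mu = rep(mus, each = 3))
    qm <- matrix(q, nrow = 3)
    obj <- (qm[1, ] - q1)^2 + (qm[2, ] - median)^2 + (qm[3, ] - q3)^2
    k <- which.min(obj)
    if (obj[k] < best_obj) {
      best_obj <- obj[k]
      best <- list(size = s, mu = mus[k],
                   q = qm[, k])
    }
  }
  list(size = best$size, mu = best$mu,
       achieved = setNames(best$q, c("q1", "median", "q3")))
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  pl <- pnorm(lower, mean, sd); pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

#' Generate a synthetic patient registry
#'
#' Draws `n` records per arm from the cohort specification's marginal
#' distributions. Identical `(spec, seed)` gives byte-identical output.
#'
#' @param spec Cohort specification (`params$cohort_spec`), or a subset of
#'   its arms.
#' @param seed Integer seed.
#' @param n_per_arm Optional named vector overriding each arm's `n` (e.g. to
#'   generate large samples for marginal checks).
#' @return Data frame, one row per patient: `id`, `arm`, `age`, `sex`,
#'   `nihss`, `core_volume`, `perfusion_lesion_volume`, `penumbra_volume`,
#'   `occlusion_site`, `onset_to_imaging`, `treatment`, `mrs_90d`.
#' @export
generate_registry <- function(spec, seed = 1L, n_per_arm = NULL) {
  set.seed(seed)
  bounds <- unlist(spec$age_bounds)
  ob <- unlist(spec$onset_bounds)
  out <- lapply(names(spec$arms), function(arm) {
    a <- spec$arms[[arm]]
    mrs_p <- unlist(a$mrs_counts)
    if (any(mrs_p < 0) || sum(mrs_p) <= 0) {
      stop("invalid mRS probability vector in arm '", arm, "'")
    }
    mrs_p <- mrs_p / sum(mrs_p)
    n <- if (!is.null(n_per_arm) && arm %in% names(n_per_arm)) {
      n_per_arm[[arm]]
    } else a$size

    age <- rtrunc_norm(n, a$age$mean, a$age$sd, bounds[1], bounds[2])
    sex <- ifelse(runif(n) < a$male_prop, "male", "female")
    nb <- fit_nbinom_quantiles(a$nihss$median, a$nihss$q1, a$nihss$q3)
    nihss <- pmin(rnbinom(n, size = nb$size, mu = nb$mu), 42L)
    cap <- if (is.null(spec$volume_cap_ml)) 600 else spec$volume_cap_ml
    cfit <- fit_lognormal_quantiles(a$core$median, a$core$q1, a$core$q3)
    core <- pmin(rlnorm(n, cfit$meanlog, cfit$sdlog), cap)
    pfit <- fit_lognormal_quantiles(a$penumbra$median, a$penumbra$q1, a$penumbra$q3)
    penumbra <- pmin(rlnorm(n, pfit$meanlog, pfit$sdlog), cap)
    onset <- rtrunc_norm(n, a$onset_to_ctp$mean, a$onset_to_ctp$sd, ob[1], ob[2])
    occl <- ifelse(runif(n) < a$p_ica, "ICA", "M1")
    tp <- unlist(a$treatment_probs)
    treatment <- names(tp)[findInterval(runif(n), cumsum(tp),
                                        rightmost.closed = TRUE) + 1L]
    treatment[treatment == "none"] <- "none"
    mrs <- findInterval(runif(n), cumsum(mrs_p)) ; mrs[mrs > 6] <- 6L
    data.frame(
      id = paste0(arm, "_", seq_len(n)),
      arm = arm,
      age = age,
      sex = sex,
      nihss = as.integer(nihss),
      core_volume = core,
      perfusion_lesion_volume = core + penumbra,
      penumbra_volume = penumbra,
      occlusion_site = occl,
      onset_to_imaging = onset,
      treatment = treatment,
      mrs_90d = as.integer(mrs),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Cohort summary in the style of a baseline-characteristics table
#'
#' Per-arm n, mean (SD) for age and onset time, median (IQR) for NIHSS and
#' volumes, counts (%) for sex, occlusion site, treatment type and the
#' Day-90 mRS distribution. Deterministic given the records.
#'
#' @param records Registry data frame from [generate_registry()].
#' @return Data frame with one row per (arm, statistic).
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || !nrow(records)) stop("empty cohort")
  arms <- unique(records$arm)
  rows <- list()
  fmt_msd <- function(x) sprintf("%.1f (%.2f)", mean(x), if (length(x) > 1) sd(x) else 0)
  fmt_miqr <- function(x) sprintf("%.0f (%.0f-%.0f)", median(x),
                                  quantile(x, 0.25), quantile(x, 0.75))
  fmt_n <- function(k, n) sprintf("%d (%.1f%%)", k, 100 * k / n)
  for (arm in arms) {
    d <- records[records$arm == arm, ]
    n <- nrow(d)
    add <- function(stat, value) {
      rows[[length(rows) + 1]] <<- data.frame(arm = arm, n = n, statistic = stat,
                                              value = value, stringsAsFactors = FALSE)
    }
    add("age_mean_sd", fmt_msd(d$age))
    add("male_n_pct", fmt_n(sum(d$sex == "male"), n))
    add("nihss_median_iqr", fmt_miqr(d$nihss))
    add("core_median_iqr", fmt_miqr(d$core_volume))
    add("perfusion_median_iqr", fmt_miqr(d$perfusion_lesion_volume))
    add("penumbra_median_iqr", fmt_miqr(d$penumbra_volume))
    add("onset_to_ctp_mean_sd", fmt_msd(d$onset_to_imaging))
    add("ica_n_pct", fmt_n(sum(d$occlusion_site == "ICA"), n))
    for (tt in c("EVT_plus_tPA", "EVT_only", "tPA_only", "none")) {
      add(paste0("treatment_", tt), fmt_n(sum(d$treatment == tt), n))
    }
    for (k in 0:6) add(paste0("mrs_", k), fmt_n(sum(d$mrs_90d == k), n))
  }
  do.call(rbind, rows)
}

#' Write / read a registry as delimited text
#'
#' @param records Registry data frame.
#' @param path CSV path.
#' @return `read_registry` returns the registry data frame.
#' @export
write_registry <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "nihss", "core_volume",
            "perfusion_lesion_volume", "penumbra_volume", "occlusion_site",
            "onset_to_imaging", "treatment", "mrs_90d")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("registry missing columns: ", paste(miss, collapse = ", "))
  d
}
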