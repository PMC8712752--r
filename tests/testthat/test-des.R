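test_that("null process reaches the horizon with no events", {
  p <- null_params()
  tr <- simulate_patient(2, 70, "female", p, seed = 1)
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$kind, "horizon_end")
  expect_equal(tr$events$time, 25)
  expect_true(is.na(tr$death_time))

  arm <- run_arm(make_cohort(50, mrs = 2), p, n_patients = 50, seed = 1,
                 resample = FALSE)
  expect_equal(arm$mean_ly, 25)
  expect_equal(arm$mean_deaths, 0)
  expect_equal(arm$mean_ly_discounted, discounted_flow(1, 0.03, 0, 25),
               tolerance = 1e-9)
})

test_that("forced fatal MI kills at the first event", {
  p <- null_params()
  p$hazards$mi$rate <- 50       # MI almost immediately
  p$fatality$p_fatal_mi <- 1
  tr <- simulate_patient(1, 70, "male", p, seed = 3)
  expect_equal(tr$events$kind[1], "mi")
  expect_equal(tr$events$mrs_after[1], 6L)
  expect_equal(tr$death_time, tr$events$time[1])
  expect_lt(tr$death_time, 0.5)
})

test_that("Day-90 mRS 6 is an immediate death with index costs only", {
  arm <- run_arm(make_cohort(10, mrs = 6), tp, n_patients = 10, seed = 1,
                 resample = FALSE, treatment_group = "EVT")
  expect_equal(arm$mean_qaly, 0)
  expect_equal(arm$mean_ly, 0)
  expect_equal(arm$mean_deaths, 1)
  expect_equal(arm$mean_cost, unname(tp$costs$index_acute[["EVT"]]))
  tr <- simulate_patient(6, 80, "male", tp, seed = 1)
  expect_equal(tr$events$time, 0)
  expect_equal(tr$death_time, 0)
})

test_that("traces respect ordering, death-finality and QALY <= LY", {
  cohort <- make_cohort(300, mrs = sample(0:6, 300, TRUE),
                        age = runif(300, 40, 95),
                        sex = sample(c("male", "female"), 300, TRUE))
  arm <- run_arm(cohort, tp, n_patients = 300, seed = 5, resample = FALSE,
                 keep_traces = TRUE)
  ord <- order(cohort$mrs_90d, cohort$age)
  traces <- traces_from_log(arm, cohort$mrs_90d[ord])
  for (tr in traces) {
    ev <- tr$events
    expect_gt(nrow(ev), 0)
    expect_true(all(diff(ev$time) > 0) || nrow(ev) == 1)
    last <- ev[nrow(ev), ]
    expect_true(last$mrs_after == 6L || last$kind == "horizon_end")
    # nothing after a death
    if (any(ev$mrs_after == 6L)) {
      expect_equal(which(ev$mrs_after == 6L)[1], nrow(ev))
    }
    if (last$kind == "horizon_end") expect_equal(last$time, 25)
  }
  expect_true(all(arm$per_patient$qaly <= arm$per_patient$ly_discounted + 1e-9))
  expect_true(all(arm$per_patient$ly <= 25 + 1e-12))
  dt <- arm$death_time
  expect_true(all(is.na(dt) | dt <= 25))
})

test_that("vectorised accrual equals the independent per-trace integrator", {
  cohort <- make_cohort(200, mrs = sample(0:5, 200, TRUE),
                        age = runif(200, 45, 90),
                        sex = sample(c("male", "female"), 200, TRUE))
  arm <- run_arm(cohort, tp, n_patients = 200, seed = 9, resample = FALSE,
                 keep_traces = TRUE, treatment_group = "medical")
  ord <- order(cohort$mrs_90d, cohort$age)
  traces <- traces_from_log(arm, cohort$mrs_90d[ord])
  for (i in seq_along(traces)) {
    acc <- accrue_trace(traces[[i]], tp$costs, tp$utilities,
                        tp$discount_rate, treatment_group = "medical")
    expect_equal(arm$per_patient$cost[i], acc$cost, tolerance = 1e-9)
    expect_equal(arm$per_patient$qaly[i], acc$qaly, tolerance = 1e-9)
    expect_equal(arm$per_patient$ly[i], acc$ly, tolerance = 1e-9)
  }
})

test_that("with background mortality only, survival matches the closed form", {
  p <- background_only_params()
  n <- 1e5
  arm <- run_arm(make_cohort(n, mrs = 3, age = 68, sex = "female"), p,
                 n_patients = n, seed = 12, resample = FALSE)
  grid <- 1:25
  s_emp <- vapply(grid, function(g)
    mean(is.na(arm$death_time) | arm$death_time > g), numeric(1))
  s_cf <- mortality_survival(grid, 68, "female", p$mortality, cause = "noncvd")
  expect_lt(max(abs(s_emp - s_cf)), 0.01)
})

test_that("simulation is exactly reproducible for a fixed seed", {
  cohort <- make_cohort(500, mrs = sample(0:6, 500, TRUE))
  a <- run_arm(cohort, tp, n_patients = 400, seed = 77)
  b <- run_arm(cohort, tp, n_patients = 400, seed = 77)
  expect_identical(a$per_patient, b$per_patient)
  expect_identical(a$death_time, b$death_time)
  c <- run_arm(cohort, tp, n_patients = 400, seed = 78)
  expect_false(identical(a$mean_cost, c$mean_cost))
})

test_that("calibration round trip is reproduced in full simulation", {
  # only the combined MI/CVD-death process active, no case fatality on MI:
  # cumulative incidence of any event at 5 y must equal the calibrated risk
  p <- null_params()
  comb <- calibrate_exponential(0.174, 5)
  p$hazards$mi$rate <- comb / 2
  p$hazards$cvd_death$rate <- comb / 2
  for (cc in c("cvd_male", "cvd_female")) p$mortality[[cc]] <- rep(comb / 2, nrow(p$mortality))
  p$fatality$p_fatal_mi <- 0
  n <- 5e4
  arm <- run_arm(make_cohort(n, mrs = 1, age = 60), p, n_patients = n,
                 seed = 31, resample = FALSE, keep_traces = TRUE)
  first_ev <- arm$event_log[!duplicated(arm$event_log$patient), ]
  had_event <- first_ev$kind %in% c("mi", "cvd_death") & first_ev$time <= 5
  se <- sqrt(0.174 * 0.826 / n)
  expect_lt(abs(mean(had_event) - 0.174), 3 * se)
})

test_that("recurrent stroke worsens state monotonically and accrues severity costs", {
  p <- null_params()
  p$hazards$recurrent_stroke$rate <- 0.5
  p$fatality$p_fatal_recurrent_stroke <- 0
  cohort <- make_cohort(2000, mrs = 2)
  arm <- run_arm(cohort, p, n_patients = 2000, seed = 15, resample = FALSE,
                 keep_traces = TRUE)
  lg <- arm$event_log
  rs <- lg[lg$kind == "recurrent_stroke", ]
  expect_gt(nrow(rs), 0)
  # survivors never improve below their prior state
  expect_true(all(rs$mrs_after >= 2))
  # doubling n changes the mean by less than 2 Monte-Carlo SEs
  arm2 <- run_arm(cohort, p, n_patients = 4000, seed = 16)
  expect_lt(abs(arm2$mean_qaly - arm$mean_qaly),
            2 * (arm$se_qaly + arm2$se_qaly))
})

test_that("gompertz recurrence process is accepted by the engine", {
  p <- tp
  arm <- run_arm(make_cohort(500, mrs = 2), p, n_patients = 500, seed = 21,
                 resample = FALSE, hazard_rs = p$hazards$recurrent_stroke_alt)
  expect_gt(arm$mean_stroke, 0)
  expect_true(all(arm$per_patient$qaly <= arm$per_patient$ly_discounted + 1e-9))
})

test_that("common random numbers reduce the variance of arm differences", {
  cohortA <- make_cohort(1000, mrs = 2, age = 68)
  cohortB <- make_cohort(1000, mrs = 4, age = 70)
  reps <- 24
  d_crn <- numeric(reps); d_ind <- numeric(reps)
  for (k in seq_len(reps)) {
    a <- run_arm(cohortA, tp, n_patients = 1000, seed = 1000 + k, resample = FALSE)
    b1 <- run_arm(cohortB, tp, n_patients = 1000, seed = 1000 + k, resample = FALSE)
    b2 <- run_arm(cohortB, tp, n_patients = 1000, seed = 5000 + k, resample = FALSE)
    d_crn[k] <- a$mean_qaly - b1$mean_qaly
    d_ind[k] <- a$mean_qaly - b2$mean_qaly
  }
  expect_lt(var(d_crn), var(d_ind))
})
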