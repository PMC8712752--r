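test_that("incremental analysis classifies the reference worked examples", {
  b <- benchmark_base_case()
  r <- incremental(b$EVT_DEFUSE3_neg, b$MED_DEFUSE3_pos, wtp = 50000)
  expect_equal(r$delta_cost, 59302 - 50347)
  expect_equal(r$delta_qaly, 6.03 - 7.05, tolerance = 1e-12)
  expect_equal(r$classification, "dominated")

  r2 <- incremental(b$EVT_DAWN_neg, b$MED_DAWN_pos, wtp = 50000)
  expect_equal(r2$delta_cost, 56788 - 47517)
  expect_equal(r2$delta_qaly, 5.59 - 7.02, tolerance = 1e-12)
  expect_equal(r2$classification, "dominated")

  # ICER below threshold but more deaths: mortality override kicks in
  r3 <- incremental(b$EVT_DAWN_neg, b$MED_DAWN_neg, wtp = 50000)
  expect_equal(r3$icer, (56788 - 43801) / (5.59 - 4.64), tolerance = 1e-9)
  expect_equal(r3$classification, "mortality_dominated")
  r3b <- incremental(b$EVT_DAWN_neg, b$MED_DAWN_neg, wtp = 50000,
                     mortality_override = FALSE)
  expect_equal(r3b$classification, "cost_effective")

  # positive comparisons are cost-effective at the threshold
  r4 <- incremental(b$EVT_DEFUSE3_pos, b$MED_DEFUSE3_pos, wtp = 50000)
  expect_equal(r4$icer, (70810 - 50347) / (8.81 - 7.05), tolerance = 1e-9)
  expect_equal(r4$classification, "cost_effective")
})

test_that("incremental analysis is antisymmetric and handles identity", {
  a <- arm_summary("A", 60000, 7.2, deaths = 0.6)
  b <- arm_summary("B", 50000, 6.1, deaths = 0.7)
  f <- incremental(a, b, wtp = 50000)
  g <- incremental(b, a, wtp = 50000)
  expect_equal(f$delta_cost, -g$delta_cost)
  expect_equal(f$delta_qaly, -g$delta_qaly)
  expect_equal(f$nmb, -g$nmb)
  expect_equal(f$icer, g$icer)  # ratio is invariant under sign flips

  h <- incremental(a, a, wtp = 50000)
  expect_true(is.na(h$icer))
  expect_equal(h$nmb, 0)

  dom <- incremental(arm_summary("A", 40000, 8), arm_summary("B", 50000, 6))
  expect_equal(dom$classification, "dominant")
})

test_that("death counts scale to events per 10,000 patients", {
  expect_equal(deaths_per_10k(arm_summary("x", 0, 0, deaths = 0.730)), 7300L)
  expect_equal(deaths_per_10k(arm_summary("x", 0, 0, deaths = 0.752)), 7520L)
  expect_equal(deaths_per_10k(arm_summary("x", 0, 0, deaths = 0)), 0L)
  expect_error(deaths_per_10k(arm_summary("x", 0, 0, deaths = 1.2)))
})

test_that("acceptability curve limits and hand counts", {
  pl <- data.frame(delta_cost = c(1, 3), delta_qaly = c(1, 1))
  expect_equal(ceac(pl, 2)$prob_cost_effective, 0.5)
  # dominant cloud
  pl2 <- data.frame(delta_cost = -abs(rnorm(50)), delta_qaly = abs(rnorm(50)))
  expect_true(all(ceac(pl2, c(0, 1e4, 1e5))$prob_cost_effective == 1))
  # dominated cloud
  pl3 <- data.frame(delta_cost = abs(rnorm(50)), delta_qaly = -abs(rnorm(50)))
  expect_true(all(ceac(pl3, c(0, 1e4, 1e5))$prob_cost_effective == 0))
  # limits: w = 0 -> P(dC < 0); w -> Inf -> P(dE > 0)
  set.seed(55)
  pl4 <- data.frame(delta_cost = rnorm(500, 1000, 5000),
                    delta_qaly = rnorm(500, 0.1, 1))
  cc <- ceac(pl4, c(0, 1e12))
  expect_equal(cc$prob_cost_effective[1], mean(pl4$delta_cost < 0))
  expect_equal(cc$prob_cost_effective[2], mean(pl4$delta_qaly > 0))
  expect_equal(nrow(ceac(pl4, numeric(0))), 0)
})

test_that("one-way sensitivity analysis orders parameters by spread", {
  # cheap but real pipeline: small paired simulation, NMB outcome
  cohA <- make_cohort(300, mrs = 1, treatment = "EVT_only")
  cohB <- make_cohort(300, mrs = 4, treatment = "none")
  run_fn <- function(pp) {
    a <- run_arm(cohA, pp, n_patients = 300, seed = 9, resample = FALSE)
    b <- run_arm(cohB, pp, n_patients = 300, seed = 9, resample = FALSE)
    incremental(a, b, wtp = 50000)$nmb
  }
  ranges <- data.frame(
    parameter = c("discount_rate", "p_fatal_recurrent_stroke",
                  "cost_index_evt", "cost_acute_stroke_scale"),
    low = c(0, 0.10, 32000, 1), high = c(0.05, 0.30, 32000, 1))
  tor <- one_way_dsa(tp, run_fn, ranges)
  expect_equal(nrow(tor), 4)
  expect_true(all(diff(tor$spread) <= 0))
  # zero-width ranges produce zero spread and rank last
  expect_true(all(tor$parameter[tor$spread == 0] %in%
                    c("cost_index_evt", "cost_acute_stroke_scale")))
  # non-bracketing range is a configuration error
  bad <- data.frame(parameter = "discount_rate", low = 0.05, high = 0.10)
  expect_error(one_way_dsa(tp, run_fn, bad), "bracket")
})

test_that("discounting sensitivity is monotone in every arm", {
  coh <- make_cohort(400, mrs = sample(0:5, 400, TRUE))
  q <- vapply(c(0, 0.05), function(r) {
    pp <- tp; pp$discount_rate <- r
    run_arm(coh, pp, n_patients = 400, seed = 3, resample = FALSE)$mean_qaly
  }, numeric(1))
  expect_gt(q[1], q[2])
})

test_that("degenerate PSA manifest collapses the plane to the base case", {
  p <- tp
  p$psa_manifest$cv <- 0
  cohA <- make_cohort(200, mrs = 1, treatment = "EVT_only")
  cohB <- make_cohort(200, mrs = 4, treatment = "none")
  out <- run_psa(cohA, cohB, p, n_draws = 4, n_per_arm = 200, seed = 10,
                 resample = FALSE, wtp_grid = 50000)
  expect_equal(nrow(out$plane), 4)
  expect_true(all(abs(out$plane$delta_cost - out$plane$delta_cost[1]) < 1e-9))
  expect_true(all(abs(out$plane$delta_qaly - out$plane$delta_qaly[1]) < 1e-9))
})

test_that("PSA draws respect each family's support and monotone utilities", {
  set.seed(1)
  for (k in 1:20) {
    pd <- draw_psa_params(tp, seed = k)
    u <- pd$utilities$by_mrs
    expect_true(all(u[1:6] > 0 & u[1:6] < 1))
    expect_true(all(diff(u[1:6]) <= 0))
    expect_equal(u[7], 0)
    expect_true(pd$fatality$p_fatal_mi > 0 && pd$fatality$p_fatal_mi < 1)
    expect_true(all(pd$costs$acute_recurrent_stroke >= 0))
    expect_gt(pd$hazards$recurrent_stroke$rate, 0)
    expect_true(all(pd$mortality$cvd_male > 0))
  }
  # reproducible given the seed
  expect_equal(draw_psa_params(tp, 3)$utilities$by_mrs,
               draw_psa_params(tp, 3)$utilities$by_mrs)
})

test_that("validation report computes survival against its anchors", {
  p <- null_params()
  coh <- make_cohort(1000, mrs = c(rep(6, 300), rep(2, 700)))
  arm <- run_arm(coh, p, n_patients = 1000, seed = 2, resample = FALSE)
  v <- validate_long_term(arm)
  expect_equal(v$survival_5y, 0.7)
  expect_equal(unname(v$survival_anchors["reference_model"]), 0.518)
  arm5 <- run_arm(coh, p, n_patients = 1000, seed = 2, resample = FALSE,
                  horizon = 5)
  v2 <- validate_long_term(arm, arm5)
  expect_equal(v2$qaly_5y, arm5$mean_qaly)
})

test_that("base-case pipeline produces eight strategies and six comparisons", {
  bc <- run_base_case(tp, n_patients = 800, seed = 4)
  expect_equal(nrow(bc$summary), 8)
  expect_equal(nrow(bc$incrementals), 6)
  expect_true(all(bc$summary$qaly <= bc$summary$ly + 1e-9))
  expect_true(all(bc$summary$deaths >= 0 & bc$summary$deaths <= 1))
  # rerun with the same seed is identical
  bc2 <- run_base_case(tp, n_patients = 800, seed = 4)
  expect_identical(bc$summary, bc2$summary)
})
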