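test_that("null data yields a null propensity model", {
  set.seed(31)
  n <- 2000
  d <- data.frame(age = rnorm(n, 70, 10), sex = sample(c("male", "female"), n, TRUE),
                  nihss = sample(5:25, n, TRUE), core_volume = rlnorm(n, 3, 0.8))
  treated <- runif(n) < 0.4   # independent of covariates
  m <- fit_propensity(d, treated = treated)
  expect_true(all(m$scores > 0 & m$scores < 1))
  expect_lt(abs(mean(m$scores) - mean(treated)), 0.02)
  expect_lt(max(abs(m$scores - mean(treated))), 0.1)
})

test_that("logistic MLE matches a hand-coded likelihood optimum", {
  d <- data.frame(x1 = c(0.1, 1.4, 1.2, 2.0, 0.3, 0.6, 2.5, 0.8),
                  x2 = c(1.0, 0.2, 0.7, 1.8, 2.2, 0.1, 1.1, 0.9))
  treated <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  m <- fit_propensity(d, covariates = c("x1", "x2"), treated = treated)
  # independent oracle: direct likelihood maximisation with analytic gradient
  nll <- function(b) {
    eta <- b[1] + b[2] * d$x1 + b[3] * d$x2
    sum(log1p(exp(eta))) - sum(eta[treated])
  }
  grad <- function(b) {
    eta <- b[1] + b[2] * d$x1 + b[3] * d$x2
    p <- 1 / (1 + exp(-eta))
    r <- p - treated
    c(sum(r), sum(r * d$x1), sum(r * d$x2))
  }
  opt <- optim(c(0, 0, 0), nll, grad, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(m$coefficients), opt$par, tolerance = 1e-4)
})

test_that("perfect separation is diagnosed with the separating covariate", {
  d <- data.frame(age = c(1:5, 101:105), core_volume = rnorm(10))
  treated <- rep(c(FALSE, TRUE), each = 5)
  expect_error(fit_propensity(d, covariates = c("age", "core_volume"),
                              treated = treated),
               "separat")
  expect_error(fit_propensity(d[1:3, ], covariates = "age",
                              treated = c(TRUE, TRUE, TRUE)),
               "at least 2")
})

test_that("nearest-neighbour matching is deterministic, respects caliper and replacement", {
  mk <- function(scores, treated) list(scores = scores, treated = treated)
  # equidistant tie: deterministic given the seed, pair distance 0.1
  m <- mk(c(0.8, 0.7, 0.9), c(TRUE, FALSE, FALSE))
  s1 <- nearest_neighbor_match(m, seed = 4)
  s2 <- nearest_neighbor_match(m, seed = 4)
  expect_identical(s1$pairs, s2$pairs)
  expect_equal(nrow(s1$pairs), 1)
  expect_equal(s1$pairs$distance, 0.1, tolerance = 1e-12)

  # zero caliper: only exactly equal scores pair up
  m2 <- mk(c(0.5, 0.5, 0.3, 0.31), c(TRUE, FALSE, TRUE, FALSE))
  s <- nearest_neighbor_match(m2, caliper = 0)
  expect_equal(nrow(s$pairs), 1)
  expect_equal(s$pairs$score_control, 0.5)
  expect_equal(s$unmatched_treated, 3)

  # without replacement: controls are exhausted, |pairs| <= min(group sizes)
  set.seed(8)
  n_t <- 133; n_c <- 98
  m3 <- mk(c(runif(n_t), runif(n_c)), rep(c(TRUE, FALSE), c(n_t, n_c)))
  s3 <- nearest_neighbor_match(m3, seed = 2)
  expect_equal(nrow(s3$pairs), n_c)
  expect_equal(length(s3$unmatched_treated), n_t - n_c)
  expect_false(any(duplicated(s3$pairs$control_id)))
  expect_false(any(duplicated(s3$pairs$treated_id)))

  # with replacement every treated is matched
  s4 <- nearest_neighbor_match(m3, with_replacement = TRUE, seed = 2)
  expect_equal(nrow(s4$pairs), n_t)

  # caliper bounds the worst pair distance
  s5 <- nearest_neighbor_match(m3, caliper = 0.01, seed = 2)
  expect_true(all(s5$pairs$distance <= 0.01))
})

test_that("standardized mean difference matches the closed form", {
  x <- c(1, 3, 2, 6); tr <- c(TRUE, TRUE, FALSE, FALSE)
  pooled <- sqrt((var(c(1, 3)) + var(c(2, 6))) / 2)
  expect_equal(smd(x, tr), (2 - 4) / pooled, tolerance = 1e-12)
  expect_warning(z <- smd(c(1, 1, 2, 2), tr), "zero pooled SD")
  expect_equal(z, 0)
})

test_that("matching improves covariate balance on a shifted cohort", {
  set.seed(77)
  n <- 400
  d <- data.frame(
    age = c(rnorm(n / 2, 75, 8), rnorm(n / 2, 65, 8)),
    nihss = sample(5:25, n, TRUE))
  treated <- rep(c(TRUE, FALSE), each = n / 2)
  m <- fit_propensity(d, covariates = c("age", "nihss"), treated = treated)
  s <- nearest_neighbor_match(m, caliper = 0.05, seed = 3)
  b <- balance_diagnostics(s, d, m)
  age_row <- b[b$covariate == "age", ]
  expect_lt(abs(age_row$smd_after), abs(age_row$smd_before))
  expect_gt(abs(age_row$smd_before), 0.5)

  # identical treated/control samples: all SMDs zero after matching
  d2 <- data.frame(age = rep(c(60, 70, 80), 2), nihss = rep(c(10, 15, 20), 2))
  m2 <- list(scores = rep(c(0.4, 0.5, 0.6), 2),
             treated = rep(c(TRUE, FALSE), each = 3),
             covariates = c("age", "nihss"))
  s2 <- nearest_neighbor_match(m2, seed = 1)
  b2 <- balance_diagnostics(s2, d2, m2)
  expect_true(all(abs(b2$smd_after) < 1e-12))
})

test_that("randomized treatment gives centred post-matching SMDs", {
  set.seed(101)
  reps <- 40
  smds <- replicate(reps, {
    n <- 200
    d <- data.frame(age = rnorm(n, 70, 10))
    treated <- runif(n) < 0.5
    m <- suppressWarnings(fit_propensity(d, covariates = "age", treated = treated))
    s <- nearest_neighbor_match(m, seed = 1)
    balance_diagnostics(s, d, m)$smd_after
  })
  expect_lt(abs(mean(smds)), 0.05)
})
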