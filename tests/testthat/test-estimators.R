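test_that("wald_ratios computes first-order ratio estimates", {
  set <- make_set(bx = 0.02, sx = 0.003, by = -0.01, sy = 0.03)
  r <- wald_ratios(set)
  expect_equal(r$theta, -0.5)
  expect_equal(r$se, 1.5)
  expect_equal(r$weight, 1.5^-2)

  # null outcome effect
  expect_equal(wald_ratios(make_set(0.02, 0.003, 0, 0.03))$theta, 0)

  # joint sign flip leaves the ratio unchanged
  expect_equal(wald_ratios(make_set(-0.02, 0.003, 0.01, 0.03))$theta, -0.5)

  expect_error(wald_ratios(make_set(c(0.02, 0), c(0.003, 0.003),
                                    c(0, 0), c(0.03, 0.03))),
               "zero exposure effect.*rs0002")
})

test_that("IVW matches degenerate cases and weight additivity", {
  # identical ratios: exact estimate, zero heterogeneity
  set <- make_set(bx = c(0.02, 0.04), sx = c(0.003, 0.003),
                  by = c(0.006, 0.012), sy = c(0.02, 0.02))
  est <- mr_ivw(set, "fixed")
  expect_equal(est$theta, 0.3)
  expect_equal(est$Q, 0)

  # J duplicated copies: same estimate, fixed SE shrunk by sqrt(J)
  J <- 9L
  dup <- make_set(rep(0.02, J), rep(0.003, J), rep(0.008, J), rep(0.02, J))
  one <- make_set(rep(0.02, 2), rep(0.003, 2), rep(0.008, 2), rep(0.02, 2))
  e_dup <- mr_ivw(dup, "fixed"); e_one <- mr_ivw(one, "fixed")
  expect_equal(e_dup$theta, e_one$theta)
  expect_equal(e_dup$se, e_one$se * sqrt(2 / J))

  expect_error(mr_ivw(make_set(0.02, 0.003, 0.01, 0.02)), ">= 2 instruments")
})

test_that("IVW equals the origin-constrained WLS oracle", {
  for (seed in 1:20) {
    set <- random_set(20L, seed)
    oracle <- oracle_wls_origin(set$beta_exposure, set$beta_outcome,
                                set$se_outcome)
    est <- mr_ivw(set, "fixed")
    expect_equal(est$theta, oracle$theta, tolerance = 1e-10)
    expect_equal(est$se, oracle$se_fixed, tolerance = 1e-10)
    # random-effects model shares the point estimate
    expect_equal(mr_ivw(set, "random")$theta, est$theta)
  }
})

test_that("IVW is invariant to joint sign flips of instrument subsets", {
  set <- random_set(15L, 99)
  flipped <- set
  idx <- c(2, 5, 11)
  flipped$beta_exposure[idx] <- -flipped$beta_exposure[idx]
  flipped$beta_outcome[idx] <- -flipped$beta_outcome[idx]
  expect_equal(mr_ivw(flipped, "fixed")$theta, mr_ivw(set, "fixed")$theta)
  # Egger slope likewise, given its positive-orientation rule
  expect_equal(mr_egger(flipped)$slope$theta, mr_egger(set)$slope$theta)
})

test_that("weighted median interpolates the 50th weighted percentile", {
  # equal weights, theta = (1, 2, 9): the middle value
  set <- make_set(bx = c(0.01, 0.01, 0.01), sx = rep(0.002, 3),
                  by = c(0.01, 0.02, 0.09), sy = rep(0.01, 3))
  est <- suppressWarnings(mr_weighted_median(set, n_boot = 200, seed = 1))
  expect_equal(est$theta, 2)

  # all ratios equal: estimate exact, bootstrap SE small
  setc <- make_set(rep(0.05, 5), rep(0.001, 5), rep(0.015, 5),
                   rep(1e-4, 5))
  est <- mr_weighted_median(setc, n_boot = 200, seed = 1)
  expect_equal(est$theta, 0.3)
  expect_lt(est$se, 0.01)

  expect_warning(mr_weighted_median(set, n_boot = 50, seed = 1),
                 "n_boot < 100")
  expect_error(mr_weighted_median(make_set(0.01, 0.1, 0.01, 0.1)),
               ">= 3 instruments")
})

test_that("equal-weight weighted median equals the sample median (odd J)", {
  for (seed in 1:10) {
    withr::local_seed(seed)
    J <- 11L
    theta <- rnorm(J)
    # equal ratio weights: bx and sy constant
    set <- make_set(rep(0.02, J), rep(0.002, J), 0.02 * theta,
                    rep(0.015, J))
    est <- suppressWarnings(mr_weighted_median(set, n_boot = 100, seed = 1))
    expect_equal(est$theta, median(theta), tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers an exact line and flags collinearity", {
  bx <- c(0.01, 0.02, 0.03, 0.05)
  a <- 0.004; b <- -0.6
  set <- make_set(bx, rep(0.002, 4), a + b * bx, rep(0.01, 4))
  fit <- mr_egger(set)
  expect_equal(fit$intercept, a, tolerance = 1e-12)
  expect_equal(fit$slope$theta, b, tolerance = 1e-12)

  expect_error(mr_egger(make_set(rep(0.02, 4), rep(0.002, 4),
                                 c(0.01, 0.02, 0.01, 0.02), rep(0.01, 4))),
               "collinearity")
  expect_error(mr_egger(make_set(c(0.01, 0.02), rep(0.002, 2),
                                 c(0.01, 0.02), rep(0.01, 2))),
               ">= 3 instruments")
})

test_that("balanced pleiotropy triggers the Egger intercept test ~5%", {
  withr::local_seed(31)
  J <- 50L
  hits <- replicate(1000, {
    bx <- abs(rnorm(J, 0.02, 0.006)) + 0.005
    sy <- runif(J, 0.01, 0.02)
    alpha <- rnorm(J, 0, 0.01)           # balanced: mean zero
    by <- rnorm(J, 0.2 * bx + alpha, sy)
    # pleiotropy inflates residual variance; the multiplicative model
    # absorbs it, so the z-test keeps its nominal size
    fit <- mr_egger(make_set(bx, rep(0.002, J), by, sy))
    abs(fit$intercept / fit$intercept_se) > qnorm(0.975)
  })
  rate <- mean(hits)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("Egger intercept recovers directional pleiotropy; IVW is biased", {
  withr::local_seed(77)
  mu <- 0.02; theta_true <- 0.2; J <- 60L
  reps <- 300L
  res <- replicate(reps, {
    bx <- abs(rnorm(J, 0.02, 0.006)) + 0.005
    sy <- runif(J, 0.01, 0.02)
    alpha <- rnorm(J, mu, 0.005)
    by <- rnorm(J, theta_true * bx + alpha, sy)
    set <- make_set(bx, rep(0.002, J), by, sy)
    c(intercept = mr_egger(set)$intercept, ivw = mr_ivw(set)$theta)
  })
  mc_se <- sd(res["intercept", ]) / sqrt(reps)
  expect_lt(abs(mean(res["intercept", ]) - mu), 4 * mc_se)
  # IVW absorbs alpha/gamma into the slope: biased well away from truth
  expect_gt(mean(res["ivw", ]) - theta_true, 0.3)
})

test_that("odds-ratio conversion matches the published back-transform", {
  # theta = 0: OR exactly 1
  null <- mr_estimate("ivw_fixed", 0, 0.1, 10)
  expect_equal(to_odds_ratio(null)$odds_ratio, 1)

  # the published IVW row: theta -0.616 with CI (-0.891, -0.341)
  est <- mr_estimate("ivw_fixed", -0.616, 0.2755 / qnorm(0.975), 111)
  or <- to_odds_ratio(est)
  expect_equal(round(or$odds_ratio, 2), 0.54)
  expect_equal(round(or$ci_low, 2), 0.41)
  expect_equal(round(or$ci_high, 2), 0.71)

  # OR(theta) * OR(-theta) = 1
  a <- mr_estimate("ivw_fixed", 0.37, 0.1, 10)
  b <- mr_estimate("ivw_fixed", -0.37, 0.1, 10)
  expect_equal(to_odds_ratio(a)$odds_ratio * to_odds_ratio(b)$odds_ratio, 1)

  # estimate invariants
  expect_lt(est$ci_low, est$ci_high)
  expect_equal(est$or_ci_low, exp(est$ci_low))
  expect_equal(est$or_ci_high, exp(est$ci_high))
})
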