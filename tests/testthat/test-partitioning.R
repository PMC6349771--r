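make_series <- function(time_h, ..., volume_ml = 100) {
  metabolite_series(time_h, list(...), volume_ml)
}

test_that("net_change converts concentration deltas to micromoles", {
  s <- make_series(c(0, 50, 100),
                   ammonium = c(1.0, 1.2, 1.5),
                   nitrate = c(12, 6, 0),
                   n2o_umol = c(0, 5, 12))
  expect_equal(net_change(s, "ammonium", 0, 100), 50)     # +0.5 mM x 100 mL
  expect_equal(net_change(s, "nitrate", 0, 100), -1200)
  expect_equal(net_change(s, "n2o_umol", 0, 100), 12)     # already per vessel
  constant <- make_series(c(0, 10, 20), nitrite = c(2, 2, 2))
  expect_equal(net_change(constant, "nitrite"), 0)
  # assimilation: negative net change preserved, not clamped
  assim <- make_series(c(0, 100), ammonium = c(1.4, 1.2))
  expect_equal(net_change(assim, "ammonium"), -20)
  expect_error(net_change(s, "acetate"), "not present")
  expect_error(net_change(s, "ammonium", 50, 50), "t_start")
})

test_that("N2O converts to the nitrogen basis by doubling", {
  expect_equal(n2o_to_nitrogen_basis(12), 24)
  expect_equal(n2o_to_nitrogen_basis(0), 0)
  expect_equal(n2o_to_nitrogen_basis(16.7), 33.4)
  expect_error(n2o_to_nitrogen_basis(-1), ">= 0")
})

test_that("pathway partition reproduces the state-transition fractions", {
  # published state transition: 13 umol NH4-N vs 24 umol N2O-N
  p <- partition_pathways(13, 24)
  expect_equal(p$f_amm, 13 / 37, tolerance = 1e-12)
  expect_equal(p$f_amm + p$f_den, 1)
  expect_equal(partition_pathways(5, 0)$f_amm, 1)
  expect_warning(pneg <- partition_pathways(-5, 24), "negative")
  expect_equal(pneg$f_amm, 0)
  expect_true(pneg$clamped)
  expect_error(partition_pathways(-1, 0), "no dissimilated N")
})

test_that("fractions always sum to one when defined", {
  set.seed(3)
  for (i in 1:20) {
    p <- suppressWarnings(
      partition_pathways(stats::runif(1, -5, 40), stats::runif(1, 0, 40)))
    expect_equal(p$f_amm + p$f_den, 1)
    expect_gte(p$f_amm, 0); expect_lte(p$f_amm, 1)
  }
})

test_that("nitrogen recovery is a simple percentage", {
  expect_equal(nitrogen_recovery(37, 38), 97.4, tolerance = 0.001)
  expect_equal(nitrogen_recovery(10, 10), 100)
  expect_equal(nitrogen_recovery(0, 10), 0)
  expect_error(nitrogen_recovery(10, 0), "> 0")
})

test_that("generations come from log2 of the fold change", {
  expect_equal(round(generations_from_fold_change(3.5), 1), 1.8)
  expect_equal(generations_from_fold_change(1), 0)
  expect_equal(generations_from_fold_change(2), 1)
  expect_error(generations_from_fold_change(0), "> 0")
  # multiplicativity
  set.seed(5)
  a <- stats::runif(10, 0.5, 8); b <- stats::runif(10, 0.5, 8)
  expect_equal(generations_from_fold_change(a * b),
               generations_from_fold_change(a) + generations_from_fold_change(b))
})

test_that("growth fit is exact on noise-free exponentials across mu", {
  for (mu in c(0.01, 0.05, 0.25, 0.4, 1, 2)) {
    # sample long enough for real growth at slow mu, short enough to avoid
    # overflow at fast mu
    span <- min(60, max(6, 2 / mu))
    t <- seq(0, span, length.out = 21)
    fit <- fit_specific_growth_rate(t, 0.01 * exp(mu * t))
    expect_equal(fit$mu, mu, tolerance = 1e-8)
    expect_equal(fit$doublings_per_hour, mu / log(2), tolerance = 1e-8)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("growth fit rejects flat curves and honours fixed windows", {
  t <- 0:12
  expect_error(fit_specific_growth_rate(t, rep(0.3, 13)),
               "no exponential phase")
  # exponential then plateau: sliding window should recover the early slope
  y <- c(0.01 * exp(0.4 * 0:6), rep(0.01 * exp(0.4 * 6), 6))
  fit <- fit_specific_growth_rate(t, y)
  expect_equal(fit$mu, 0.4, tolerance = 1e-6)
  expect_lte(fit$window[2], 6)
  fx <- fit_specific_growth_rate(t, y, window_strategy = "fixed",
                                 window = c(0, 6))
  expect_equal(fx$mu, 0.4, tolerance = 1e-6)
  expect_error(fit_specific_growth_rate(t[1:3], y[1:3]), "at least 4")
})

test_that("growth-vs-partition regression behaves on collinear and null data", {
  f <- c(0.2, 0.5, 0.8)
  r <- suppressWarnings(growth_vs_partition_regression(0.1 + 0.2 * f, f))
  expect_equal(r$slope, 0.2)
  expect_equal(r$r_squared, 1)
  # shuffling f_amm against mu destroys the association
  set.seed(9)
  f2 <- stats::runif(40)
  mu2 <- 0.1 + 0.3 * f2 + stats::rnorm(40, sd = 0.01)
  shuffled <- growth_vs_partition_regression(mu2, sample(f2))
  expect_lt(shuffled$r_squared, 0.15)
  expect_gt(shuffled$p_value, 0.05)
  expect_error(growth_vs_partition_regression(c(1, 2, 3), rep(0.5, 3)),
               "degenerate")
  expect_error(growth_vs_partition_regression(1:2, c(0.1, 0.2)), "at least 3")
})

test_that("analyze_culture composes the mass balance end to end", {
  sim <- simulate_batch_culture(sim_params(f_amm_true = 0.6, seed = 31))
  an <- analyze_culture(sim$clean)
  expect_lt(abs(an$partition$f_amm - 0.6), 0.02)
  expect_gt(an$recovery_percent, 95)
  expect_lte(an$recovery_percent, 100 + 1e-6)
  expect_equal(an$growth$mu, sim$truth$mu_initial, tolerance = 0.02)
})
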