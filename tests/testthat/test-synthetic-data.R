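test_that("simulation is reproducible from its seed alone", {
  a <- simulate_batch_culture(sim_params(noise_sigma = 0.05, seed = 8))
  b <- simulate_batch_culture(sim_params(noise_sigma = 0.05, seed = 8))
  expect_identical(a$series$tracks, b$series$tracks)
  c <- simulate_batch_culture(sim_params(noise_sigma = 0.05, seed = 9))
  expect_false(identical(a$series$tracks, c$series$tracks))
  # clean tracks are independent of the observation-noise seed
  expect_identical(a$clean$tracks, c$clean$tracks)
})

test_that("noise-free simulation conserves nitrogen to < 0.1%", {
  sim <- simulate_batch_culture(sim_params(f_amm_true = 0.4, seed = 2))
  tr <- sim$clean$tracks
  v <- sim$clean$volume_ml
  last <- length(sim$clean$time_h)
  consumed_no3 <- (tr$nitrate[1] - tr$nitrate[last]) * v
  accounted <- (tr$nitrite[last] - tr$nitrite[1]) * v +
    (tr$ammonium[last] - tr$ammonium[1]) * v +
    n2o_to_nitrogen_basis(tr$n2o_umol[last] - tr$n2o_umol[1]) +
    sim$truth$assimilated_n_umol
  expect_lt(abs(consumed_no3 - accounted) / (tr$nitrate[1] * v), 0.001)
})

test_that("growth stops once nitrate is exhausted", {
  sim <- simulate_batch_culture(sim_params(seed = 4))
  expect_false(is.na(sim$truth$switch_time_h))
  od <- sim$clean$tracks$od600
  after <- sim$clean$time_h > sim$truth$switch_time_h + 1
  expect_true(any(after))
  expect_lt(diff(range(od[after])) / max(od), 1e-3)
  # nitrite is produced in phase 1 and consumed in phase 2
  no2 <- sim$clean$tracks$nitrite
  expect_gt(max(no2), 10)  # most of 12 mM nitrate appears as nitrite
  expect_lt(no2[length(no2)], max(no2))
})

test_that("halving the integrator step changes outputs by < 0.01%", {
  s1 <- simulate_batch_culture(sim_params(seed = 3))
  s2 <- simulate_batch_culture(sim_params(seed = 3, dt = 0.025))
  for (nm in names(s1$clean$tracks)) {
    a <- s1$clean$tracks[[nm]]; b <- s2$clean$tracks[[nm]]
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-4)
  }
})

test_that("pathway fractions and growth rate are recovered from the output", {
  for (f in c(0.2, 0.8)) {
    sim <- simulate_batch_culture(sim_params(f_amm_true = f, seed = 40 + f * 10))
    an <- analyze_culture(sim$series)
    expect_lt(abs(an$partition$f_amm - f), 0.02)
  }
  sim <- simulate_batch_culture(sim_params(mu_max = 0.25, noise_sigma = 0.02,
                                           seed = 77))
  fit <- fit_specific_growth_rate(sim$series$time_h, sim$series$tracks$od600)
  expect_equal(fit$mu, 0.25, tolerance = 0.025)
})

test_that("end-point panel records its design and truths", {
  panel <- generate_endpoint_panel(ratios = c(4, 2, 1, 0.5, 0.1),
                                   nitrate_mM = c(12, 1.2), seed = 6)
  expect_length(panel$cultures, 10)
  expect_equal(sort(panel$design$lactate_mM),
               sort(c(c(4, 2, 1, 0.5, 0.1) * 4,
                      c(4, 2, 1, 0.5, 0.1) * 0.4)))
  expect_equal(panel$design$f_amm_true,
               coupling_low_carbon(panel$design$lactate_mM))
  expect_error(generate_endpoint_panel(ratios = numeric(0), seed = 1),
               "empty design")
  expect_error(generate_endpoint_panel(ratios = c(1, -1), seed = 1), "> 0")
})

test_that("constant coupling yields no mu-vs-f_amm relationship", {
  panel <- generate_endpoint_panel(coupling = function(l) rep(0.5, length(l)),
                                   noise_sigma = 0.02, seed = 13)
  res <- lapply(panel$cultures, function(s) analyze_culture(s$series))
  mu <- vapply(res, function(r) if (is.null(r$growth)) NA_real_ else r$growth$mu, 0)
  fa <- vapply(res, function(r) r$partition$f_amm, 0)
  ok <- is.finite(mu)
  reg <- growth_vs_partition_regression(mu[ok], fa[ok])
  expect_gt(reg$p_value, 0.05)
})

test_that("decreasing coupling preserves the f_amm ordering across cultures", {
  panel <- generate_endpoint_panel(noise_sigma = 0.02, seed = 17)
  fa <- vapply(panel$cultures,
               function(s) analyze_culture(s$series)$partition$f_amm, 0)
  expect_gt(stats::cor(fa, panel$design$f_amm_true, method = "spearman"), 0.9)
})

test_that("protein generator plants the requested ARSC shift", {
  one <- generate_protein_set(1, 1, seed = 1)
  prof <- compute_arsc(one[[1]])
  cc <- sidechain_composition(one[[1]]$sequence)
  expect_equal(prof$c_arsc, unname(cc["sidechain_C"]))
  expect_equal(prof$n_arsc, unname(cc["sidechain_N"]))

  tilted <- generate_protein_set(30, 300, delta_c_arsc = 0.3,
                                 delta_n_arsc = 0.05, seed = 2)
  ach <- attr(tilted, "achieved")
  base <- sidechain_table()
  expect_equal(unname(ach["c_arsc"]), mean(base$sidechain_C) + 0.3,
               tolerance = 1e-4)
  expect_equal(unname(ach["n_arsc"]), mean(base$sidechain_N) + 0.05,
               tolerance = 1e-4)
  profs <- compute_arsc_set(tilted)
  expect_equal(mean(profs$c_arsc), mean(base$sidechain_C) + 0.3,
               tolerance = 0.05)

  expect_error(generate_protein_set(5, 50, delta_n_arsc = 5, seed = 1),
               "infeasible")
  r1 <- generate_protein_set(3, 20, seed = 99)
  r2 <- generate_protein_set(3, 20, seed = 99)
  expect_identical(vapply(r1, `[[`, "", "sequence"),
                   vapply(r2, `[[`, "", "sequence"))
})
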