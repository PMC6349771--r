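# Ground-truthed synthetic data: a two-phase Monod batch-culture simulator
# and a planted-difference protein-family generator.
#
# The simulator encodes the qualitative physiology of a dual-pathway
# nitrite reducer grown anaerobically on lactate + nitrate:
#   phase 1 - growth on lactate with nitrate respired stoichiometrically to
#             nitrite (growth is coupled to nitrate reduction only);
#   phase 2 - once nitrate (or lactate) is exhausted growth stops, and the
#             accumulated nitrite bleeds off at a slow first-order rate,
#             split between ammonium (fraction f_amm_true, minus a small
#             assimilated share) and N2O (two nitrite per N2O).
# Nitrogen and carbon are conserved exactly in the noise-free state;
# observation noise is multiplicative, seeded, and applied only to the
# emitted tracks (the clean tracks are retained as ground truth).

#' Simulation parameters for a synthetic batch culture
#'
#' @param mu_max Maximum specific growth rate, per hour.
#' @param ks_lactate,ks_nitrate Monod half-saturation constants, mM.
#' @param yield_od Biomass yield, OD600 units per mM lactate consumed.
#' @param no3_per_lactate Mol nitrate reduced to nitrite per mol lactate
#'   consumed during growth (6 would be full catabolic oxidation of
#'   lactate; the default 4 routes one third of lactate carbon to biomass).
#' @param nitrite_turnover First-order stationary-phase nitrite consumption
#'   rate, per hour.
#' @param f_amm_true True fraction of reduced nitrite-N routed to ammonium,
#'   in `[0, 1]`.
#' @param assim_frac Fraction of pathway-produced ammonium that is
#'   re-assimilated into biomass rather than accumulating in the medium.
#' @param noise_sigma Relative (multiplicative) observation noise.
#' @param volume_ml Vessel liquid volume, mL.
#' @param lactate0,nitrate0 Initial concentrations, mM.
#' @param od0 Inoculum OD600.
#' @param t_end End of simulation, hours.
#' @param dt Fixed integrator step, hours.
#' @param obs_every Observation sampling interval, hours.
#' @param exhaustion_mM Substrate level below which a resource counts as
#'   exhausted (phase switch), mM.
#' @param seed Integer seed (mandatory).
#' @return A `sim_params` list.
#' @export
sim_params <- function(mu_max = 0.25, ks_lactate = 0.02, ks_nitrate = 0.1,
                       yield_od = 0.05, no3_per_lactate = 4,
                       nitrite_turnover = 1e-3, f_amm_true = 0.5,
                       assim_frac = 0.03, noise_sigma = 0,
                       volume_ml = 100, lactate0 = 8, nitrate0 = 12,
                       od0 = 0.005, t_end = 100, dt = 0.02, obs_every = 1,
                       exhaustion_mM = 0.01, seed) {
  if (missing(seed)) stopf("seed is required for sim_params")
  assert_scalar_num(mu_max, "mu_max", lower = 0)
  assert_scalar_num(f_amm_true, "f_amm_true", 0, 1)
  assert_scalar_num(assim_frac, "assim_frac", 0, 1)
  assert_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  assert_scalar_num(dt, "dt", lower = 1e-6)
  fields <- names(formals(sim_params))
  for (nm in c("ks_lactate", "ks_nitrate", "yield_od", "no3_per_lactate",
               "nitrite_turnover", "volume_ml", "lactate0", "nitrate0",
               "od0", "t_end", "obs_every", "exhaustion_mM"))
    assert_scalar_num(get(nm), nm, lower = 0)
  if (no3_per_lactate > 6)
    stopf("no3_per_lactate cannot exceed 6 (12 lactate electrons / 2 per nitrate)")
  structure(mget(fields), class = "sim_params")
}

# Right-hand side of the two-phase ODE. State: od, lactate, nitrate,
# nitrite, ammonium, assimilated_n (all mM except od), n2o (mM of N2O
# molecules in liquid-volume equivalents), co2_c and biomass_c (mM carbon).
#
# The growth phase and the stationary nitrite-bleed phase are blended with
# a steep smooth weight in the limiting substrate rather than a hard
# boolean: the right-hand side stays continuous, so the fixed-step RK4
# integrator keeps its 4th-order convergence across the phase transition.
sim_rhs <- function(state, p) {
  with(as.list(state), {
    # max(., 0) guards RK4 substates that transiently dip below zero
    lac <- max(lactate, 0); no3 <- max(nitrate, 0); no2 <- max(nitrite, 0)
    # smooth phase weight: ~1 while both substrates exceed the exhaustion
    # level, ~0 once either is gone (quartic sigmoid in substrate/threshold)
    wgt <- function(s) s^4 / (s^4 + p$exhaustion_mM^4)
    w <- wgt(lac) * wgt(no3)
    d <- stats::setNames(numeric(length(state)), names(state))

    mu <- w * p$mu_max * lac / (p$ks_lactate + lac) * no3 / (p$ks_nitrate + no3)
    q_lac <- mu * od / p$yield_od             # mM lactate / h
    cat_frac <- p$no3_per_lactate / 6         # share of lactate fully oxidized
    d["od"] <- mu * od
    d["lactate"] <- -q_lac
    d["nitrate"] <- -p$no3_per_lactate * q_lac
    d["nitrite"] <- p$no3_per_lactate * q_lac
    d["co2_c"] <- 3 * cat_frac * q_lac
    d["biomass_c"] <- 3 * (1 - cat_frac) * q_lac

    r <- (1 - w) * p$nitrite_turnover * no2   # mM nitrite-N / h
    d["nitrite"] <- d["nitrite"] - r
    d["ammonium"] <- p$f_amm_true * r * (1 - p$assim_frac)
    d["assimilated_n"] <- p$f_amm_true * r * p$assim_frac
    d["n2o"] <- (1 - p$f_amm_true) * r / 2
    d
  })
}

#' Simulate a two-phase batch culture
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration of the
#' switched growth / nitrite-bleed model, followed by seeded multiplicative
#' observation noise on the sampled tracks (clipped at zero). Nitrogen and
#' carbon balances of the clean state are asserted at every step.
#'
#' @param params A [sim_params()].
#' @return A `sim_output` list: `series` (noisy [metabolite_series()] with
#'   tracks lactate, nitrate, nitrite, ammonium (net, mM), n2o_umol,
#'   od600), `clean` (noise-free series), `truth` (f_amm_true, realized
#'   initial mu, phase-switch time, assimilated N, params).
#' @export
simulate_batch_culture <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  state <- c(od = p$od0, lactate = p$lactate0, nitrate = p$nitrate0,
             nitrite = 0, ammonium = 0, assimilated_n = 0, n2o = 0,
             co2_c = 0, biomass_c = 0)
  n_tot0 <- state["nitrate"] + state["nitrite"] + state["ammonium"] +
    state["assimilated_n"] + 2 * state["n2o"]
  c_tot0 <- 3 * state["lactate"] + state["co2_c"] + state["biomass_c"]

  steps <- ceiling(p$t_end / p$dt)
  times <- seq(0, by = p$dt, length.out = steps + 1L)
  out <- matrix(NA_real_, nrow = steps + 1L, ncol = length(state),
                dimnames = list(NULL, names(state)))
  out[1L, ] <- state
  switch_time <- NA_real_
  for (k in seq_len(steps)) {
    h <- p$dt
    k1 <- sim_rhs(state, p)
    k2 <- sim_rhs(state + h / 2 * k1, p)
    k3 <- sim_rhs(state + h / 2 * k2, p)
    k4 <- sim_rhs(state + h * k3, p)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    state[state < 0 & state > -1e-9] <- 0
    if (any(!is.finite(state)) || any(state < 0))
      stopf("non-finite or negative state at t = %g h; params: %s",
            times[k + 1L], paste(deparse(unclass(p)), collapse = ""))
    n_tot <- state["nitrate"] + state["nitrite"] + state["ammonium"] +
      state["assimilated_n"] + 2 * state["n2o"]
    c_tot <- 3 * state["lactate"] + state["co2_c"] + state["biomass_c"]
    if (abs(n_tot - n_tot0) > 1e-6 * max(n_tot0, 1) ||
        abs(c_tot - c_tot0) > 1e-6 * max(c_tot0, 1))
      stop("internal error: mass balance violated during integration")
    if (is.na(switch_time) &&
        (state["nitrate"] <= p$exhaustion_mM || state["lactate"] <= p$exhaustion_mM))
      switch_time <- times[k + 1L]
    out[k + 1L, ] <- state
  }

  # sample on the observation grid
  obs_t <- seq(0, p$t_end, by = p$obs_every)
  idx <- vapply(obs_t, function(t) which.min(abs(times - t)), 0L)
  obs_t <- times[idx]
  clean_tracks <- list(
    lactate = out[idx, "lactate"],
    nitrate = out[idx, "nitrate"],
    nitrite = out[idx, "nitrite"],
    ammonium = out[idx, "ammonium"],
    n2o_umol = out[idx, "n2o"] * p$volume_ml,
    od600 = out[idx, "od"]
  )
  clean <- metabolite_series(obs_t, clean_tracks, p$volume_ml)

  set.seed(p$seed)
  noisy_tracks <- lapply(clean_tracks, function(v) {
    obs <- v * (1 + p$noise_sigma * stats::rnorm(length(v)))
    pmax(obs, 0)
  })
  noisy <- metabolite_series(obs_t, noisy_tracks, p$volume_ml)

  mu0 <- p$mu_max * p$lactate0 / (p$ks_lactate + p$lactate0) *
    p$nitrate0 / (p$ks_nitrate + p$nitrate0)
  truth <- list(
    f_amm_true = p$f_amm_true,
    mu_initial = mu0,
    mu_max = p$mu_max,
    switch_time_h = switch_time,
    assimilated_n_umol = unname(state["assimilated_n"]) * p$volume_ml,
    seed = p$seed
  )
  structure(list(series = noisy, clean = clean, truth = truth, params = p),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> f_amm_true %.2f, mu0 %.3f /h, switch at %s h, sigma %g, seed %d\n",
              x$truth$f_amm_true, x$truth$mu_initial,
              format(x$truth$switch_time_h), x$params$noise_sigma,
              x$params$seed))
  print(x$series)
  invisible(x)
}

#' Default concentration -> ammonification coupling
#'
#' Decreasing logistic in lactate concentration: cultures facing low carbon
#' route more nitrite-N to ammonium. `f_amm = f_lo + (f_hi - f_lo) /
#' (1 + (lactate / l_half)^hill)`.
#'
#' @param lactate_mM Lactate concentration, mM.
#' @param f_lo,f_hi Asymptotic fractions at high / zero lactate.
#' @param l_half Lactate concentration of the half transition, mM.
#' @param hill Steepness.
#' @return Ammonification fraction in `[0, 1]`.
#' @export
coupling_low_carbon <- function(lactate_mM, f_lo = 0.15, f_hi = 0.8,
                                l_half = 0.5, hill = 2) {
  f_lo + (f_hi - f_lo) / (1 + (lactate_mM / l_half)^hill)
}

#' Generate an end-point panel across C:NO3- ratios and concentrations
#'
#' One simulated culture per (ratio, nitrate concentration) cell. Lactate
#' is set from the ratio (`lactate = ratio * nitrate / 3` for a 3-carbon
#' donor and 1-N acceptor); the true ammonification fraction comes from
#' `coupling(lactate)`; and the culture's maximum growth rate is
#' `mu_max * (1 + mu_coupling * f_amm_true)`, encoding the observed growth
#' advantage of ammonifying cultures.
#'
#' @param ratios C:NO3- ratios, > 0.
#' @param nitrate_mM Acceptor concentrations defining the resource levels
#'   (default high 12 mM and low 1.2 mM).
#' @param coupling Function lactate_mM -> f_amm_true.
#' @param mu_coupling Relative growth advantage per unit f_amm (>= 0);
#'   the default 1.5 makes a fully ammonifying culture grow up to 2.5x
#'   faster than a fully denitrifying one.
#' @param seed Master seed; each culture gets a derived seed.
#' @param ... Overrides passed to [sim_params()] (e.g. `noise_sigma`).
#' @return A `sim_panel`: list of `sim_output` plus a `design` data.frame
#'   (ratio, nitrate_mM, lactate_mM, f_amm_true, mu_max, seed).
#' @export
generate_endpoint_panel <- function(ratios = c(4, 2, 1, 0.5, 0.1),
                                    nitrate_mM = c(12, 1.2),
                                    coupling = coupling_low_carbon,
                                    mu_coupling = 1.5, seed, ...) {
  if (missing(seed)) stopf("seed is required for generate_endpoint_panel")
  if (length(ratios) == 0L || length(nitrate_mM) == 0L)
    stopf("empty design: need at least one ratio and one concentration")
  if (any(ratios <= 0)) stopf("ratios must be > 0")
  design <- expand.grid(ratio = ratios, nitrate_mM = nitrate_mM,
                        KEEP.OUT.ATTRS = FALSE)
  design$lactate_mM <- design$ratio * design$nitrate_mM / 3
  design$f_amm_true <- coupling(design$lactate_mM)
  cultures <- vector("list", nrow(design))
  dots <- list(...)
  base_mu <- dots$mu_max %||% sim_params(seed = 1)$mu_max
  dots$mu_max <- NULL
  for (i in seq_len(nrow(design))) {
    s <- derive_seed(seed, i)
    design$seed[i] <- s
    design$mu_max[i] <- base_mu * (1 + mu_coupling * design$f_amm_true[i])
    args <- utils::modifyList(list(
      lactate0 = design$lactate_mM[i], nitrate0 = design$nitrate_mM[i],
      f_amm_true = design$f_amm_true[i], mu_max = design$mu_max[i],
      seed = s), dots)
    cultures[[i]] <- simulate_batch_culture(do.call(sim_params, args))
  }
  structure(list(cultures = cultures, design = design, seed = seed),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("<sim_panel> %d cultures, master seed %d\n",
              length(x$cultures), x$seed))
  print(x$design, row.names = FALSE)
  invisible(x)
}

#' Generate protein families with a planted ARSC difference
#'
#' Sequences are drawn i.i.d. from a residue composition exponentially
#' tilted so that its expected side-chain C and N per residue differ from
#' the base composition's expectation by the requested deltas. The tilt
#' parameters are found by convex optimization of the exponential-family
#' dual; the achieved expectations are recorded in the result's
#' `"achieved"` attribute.
#'
#' @param n Number of sequences.
#' @param length Residues per sequence.
#' @param base_frequencies Named base probabilities over the 20 standard
#'   codes (default uniform); zero entries remove residues from the
#'   alphabet.
#' @param delta_c_arsc,delta_n_arsc Planted shifts of expected C- and
#'   N-ARSC relative to the base composition.
#' @param seed Integer seed.
#' @param family_label Label stored in each record.
#' @return List of [protein_record()]s with attributes `achieved`
#'   (expected c_arsc/n_arsc of the tilted composition) and `weights`.
#' @export
generate_protein_set <- function(n, length, base_frequencies = NULL,
                                 delta_c_arsc = 0, delta_n_arsc = 0,
                                 seed, family_label = "synthetic") {
  if (missing(seed)) stopf("seed is required for generate_protein_set")
  if (n < 1L || length < 1L) stopf("n and length must be >= 1")
  tab <- sidechain_table()
  p0 <- if (is.null(base_frequencies)) {
    stats::setNames(rep(1 / 20, 20), tab$code)
  } else {
    bf <- base_frequencies[tab$code]
    bf[is.na(bf)] <- 0
    if (sum(bf) <= 0) stopf("base_frequencies sum to zero")
    stats::setNames(bf / sum(bf), tab$code)
  }
  support <- p0 > 0
  C <- tab$sidechain_C; N <- tab$sidechain_N
  target_c <- sum(p0 * C) + delta_c_arsc
  target_n <- sum(p0 * N) + delta_n_arsc
  if (target_c < min(C[support]) || target_c > max(C[support]) ||
      target_n < min(N[support]) || target_n > max(N[support]))
    stopf("infeasible ARSC delta: target (C %.3f, N %.3f) outside the achievable range",
          target_c, target_n)

  w <- p0
  if (delta_c_arsc != 0 || delta_n_arsc != 0) {
    # dual of the max-entropy tilt: minimize log Z(a) - a . target (convex)
    obj <- function(a) {
      z <- p0 * exp(a[1] * C + a[2] * N)
      log(sum(z)) - a[1] * target_c - a[2] * target_n
    }
    grad <- function(a) {
      z <- p0 * exp(a[1] * C + a[2] * N)
      q <- z / sum(z)
      c(sum(q * C) - target_c, sum(q * N) - target_n)
    }
    opt <- stats::optim(c(0, 0), obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    z <- p0 * exp(opt$par[1] * C + opt$par[2] * N)
    w <- z / sum(z)
    if (abs(sum(w * C) - target_c) > 1e-4 || abs(sum(w * N) - target_n) > 1e-4)
      stopf("infeasible ARSC delta: tilt did not converge to (C %.3f, N %.3f)",
            target_c, target_n)
  }

  set.seed(seed)
  codes <- tab$code
  records <- lapply(seq_len(n), function(i) {
    seqs <- paste(sample(codes, length, replace = TRUE, prob = w), collapse = "")
    protein_record(sprintf("%s_%03d", family_label, i), seqs, family_label)
  })
  attr(records, "achieved") <- c(c_arsc = sum(w * C), n_arsc = sum(w * N))
  attr(records, "weights") <- w
  records
}
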