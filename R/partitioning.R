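# Nitrogen mass balance, pathway fractions and growth-rate estimation.
#
# All amounts are converted to micromoles through the vessel liquid volume
# (mM concentrations x mL volume = umol). N2O is always reported on the
# nitrogen basis (2 N per N2O) so that the ammonium and N2O channels are
# commensurable as "dissimilated N".

#' Construct a metabolite time series
#'
#' @param time_h Strictly increasing time points, hours.
#' @param tracks Named list of numeric concentration vectors (mM for
#'   dissolved analytes; `n2o_umol` is per-vessel micromoles; `od600` is
#'   unitless). All must have `length(time_h)`.
#' @param volume_ml Vessel liquid volume, mL.
#' @return A `metabolite_series` object.
#' @export
metabolite_series <- function(time_h, tracks, volume_ml) {
  if (any(diff(time_h) <= 0)) stopf("time points must be strictly increasing")
  assert_scalar_num(volume_ml, "volume_ml", lower = 0)
  for (nm in names(tracks)) {
    if (length(tracks[[nm]]) != length(time_h))
      stopf("track '%s' length %d does not match %d time points",
            nm, length(tracks[[nm]]), length(time_h))
    if (any(tracks[[nm]] < 0, na.rm = TRUE))
      stopf("track '%s' has negative values", nm)
  }
  structure(list(time_h = time_h, tracks = tracks, volume_ml = volume_ml),
            class = "metabolite_series")
}

#' @export
print.metabolite_series <- function(x, ...) {
  cat(sprintf("<metabolite_series> %d points over %g-%g h, %g mL; tracks: %s\n",
              length(x$time_h), min(x$time_h), max(x$time_h), x$volume_ml,
              paste(names(x$tracks), collapse = ", ")))
  invisible(x)
}

track_at <- function(series, analyte, t) {
  tr <- series$tracks[[analyte]]
  if (is.null(tr)) stopf("analyte '%s' not present in series", analyte)
  i <- which(abs(series$time_h - t) < 1e-9)
  if (length(i) == 1L) return(tr[i])
  # linear interpolation between sampled points
  if (t < min(series$time_h) || t > max(series$time_h))
    stopf("time %g h outside series range", t)
  stats::approx(series$time_h, tr, xout = t)$y
}

#' Net change of an analyte in micromoles
#'
#' `(conc(t_end) - conc(t_start)) * volume`. The sign is preserved:
#' assimilation can make the net ammonium change negative, matching how
#' signed net changes are reported for batch incubations. For the
#' per-vessel `n2o_umol` track no volume factor is applied.
#'
#' @param series A [metabolite_series()].
#' @param analyte Track name (e.g. "ammonium").
#' @param t_start,t_end Window bounds in hours, `t_start < t_end`.
#' @return Net change in micromoles.
#' @export
net_change <- function(series, analyte, t_start = min(series$time_h),
                       t_end = max(series$time_h)) {
  stopifnot(inherits(series, "metabolite_series"))
  if (t_start >= t_end) stopf("t_start must be < t_end")
  dc <- track_at(series, analyte, t_end) - track_at(series, analyte, t_start)
  if (analyte == "n2o_umol") dc else dc * series$volume_ml
}

#' Convert moles of N2O to the nitrogen basis
#'
#' @param moles_n2o Amount of N2O (any mole-like unit), >= 0.
#' @return `2 * moles_n2o` (two N atoms per N2O).
#' @export
#' @examples
#' n2o_to_nitrogen_basis(12)  # 24 umol N2O-N
n2o_to_nitrogen_basis <- function(moles_n2o) {
  if (any(moles_n2o < 0)) stopf("moles_n2o must be >= 0")
  2 * moles_n2o
}

#' Partition dissimilated nitrogen between the two pathways
#'
#' The ammonification fraction is the positive net ammonium-N change over
#' the total positively dissimilated N. A net-negative ammonium change
#' (assimilation exceeding production) contributes zero with a warning
#' flag, keeping fractions in `[0, 1]` while the signed net change remains
#' available upstream.
#'
#' @param d_nh4 Net ammonium-N change, micromoles (may be negative).
#' @param d_n2o_n N2O-N produced, micromoles, >= 0.
#' @return A `pathway_partition` list: `d_nh4`, `d_n2o_n`, `f_amm`,
#'   `f_den`, `clamped` (TRUE when a negative `d_nh4` was floored at 0).
#' @export
#' @examples
#' partition_pathways(13, 24)  # f_amm ~ 0.351
partition_pathways <- function(d_nh4, d_n2o_n) {
  if (d_n2o_n < 0) stopf("d_n2o_n must be >= 0")
  clamped <- d_nh4 < 0
  nh4_pos <- max(d_nh4, 0)
  total <- nh4_pos + d_n2o_n
  if (total <= 0) stopf("no dissimilated N: both channels are <= 0")
  if (clamped)
    warnf("net NH4+ change is negative (%g umol); treated as 0 in the fraction",
          d_nh4)
  f_amm <- nh4_pos / total
  structure(list(d_nh4 = d_nh4, d_n2o_n = d_n2o_n,
                 f_amm = f_amm, f_den = 1 - f_amm, clamped = clamped),
            class = "pathway_partition")
}

#' @export
print.pathway_partition <- function(x, ...) {
  cat(sprintf("<pathway_partition> NH4-N %+g umol, N2O-N %g umol -> f_amm %.3f, f_den %.3f%s\n",
              x$d_nh4, x$d_n2o_n, x$f_amm, x$f_den,
              if (x$clamped) " (NH4 clamped)" else ""))
  invisible(x)
}

#' Nitrogen recovery of an incubation
#'
#' @param products_n Dissimilation products recovered (NH4-N + N2O-N, and
#'   any other measured N sinks), micromoles.
#' @param n_dissimilated Total N dissimilated (e.g. nitrite consumed),
#'   micromoles, > 0.
#' @return Recovery in percent.
#' @export
nitrogen_recovery <- function(products_n, n_dissimilated) {
  if (n_dissimilated <= 0) stopf("n_dissimilated must be > 0")
  100 * products_n / n_dissimilated
}

#' Generations elapsed from a fold change in cell number
#'
#' @param fold Ratio of final to initial population size, > 0.
#' @return `log2(fold)` generations.
#' @export
#' @examples
#' generations_from_fold_change(3.5)  # 1.81
generations_from_fold_change <- function(fold) {
  if (any(fold <= 0)) stopf("fold change must be > 0")
  log2(fold)
}

#' Fit a specific growth rate from a growth curve
#'
#' Log-linear least squares on the exponential window. The default
#' `"sliding"` strategy scans all windows with at least `min_points` points
#' and `min_span_h` hours and keeps the one maximizing r-squared (ties go to
#' the longer window); `"fixed"` fits the window given in `window`.
#'
#' @param time_h Time points, hours.
#' @param signal OD600 or cell counts; only strictly positive readings are
#'   usable.
#' @param window_strategy `"sliding"` or `"fixed"`.
#' @param window Length-2 numeric `(t0, t1)` for the fixed strategy.
#' @param min_points Minimum points per window (default 4).
#' @param min_span_h Minimum window span in hours (default 3).
#' @param min_r_squared Windows below this r-squared do not count as
#'   exponential phase (default 0.98).
#' @param min_fold Sliding windows must span at least this fold increase in
#'   signal (default 1.5); this rejects spurious high-r-squared fits on
#'   near-flat stationary-phase noise.
#' @return A `growth_fit`: `mu` (per hour), `doublings_per_hour`
#'   (`mu / ln 2`), `window`, `r_squared`, `n_points`.
#' @export
#' @examples
#' t <- 0:10
#' fit_specific_growth_rate(t, 0.01 * exp(0.4 * t))$mu  # 0.4
fit_specific_growth_rate <- function(time_h, signal,
                                     window_strategy = c("sliding", "fixed"),
                                     window = NULL, min_points = 4L,
                                     min_span_h = 3, min_r_squared = 0.98,
                                     min_fold = 1.5) {
  window_strategy <- match.arg(window_strategy)
  keep <- is.finite(signal) & signal > 0
  time_h <- time_h[keep]; y <- log(signal[keep])
  n <- length(time_h)
  if (n < min_points) stopf("need at least %d positive readings", min_points)

  fit_window <- function(i, j) {
    tt <- time_h[i:j]; yy <- y[i:j]
    fit <- stats::lm.fit(cbind(1, tt), yy)
    mu <- fit$coefficients[2]
    ss_res <- sum(fit$residuals^2); ss_tot <- sum((yy - mean(yy))^2)
    r2 <- if (ss_tot <= 0) 0 else 1 - ss_res / ss_tot
    list(mu = unname(mu), r2 = r2, window = c(tt[1], tt[length(tt)]),
         n = j - i + 1L)
  }

  if (window_strategy == "fixed") {
    if (is.null(window) || length(window) != 2L)
      stopf("fixed strategy needs window = c(t0, t1)")
    idx <- which(time_h >= window[1] & time_h <= window[2])
    if (length(idx) < min_points)
      stopf("fixed window holds fewer than %d points", min_points)
    best <- fit_window(min(idx), max(idx))
  } else {
    best <- NULL
    for (i in seq_len(n - min_points + 1L)) {
      for (j in seq(i + min_points - 1L, n)) {
        if (time_h[j] - time_h[i] < min_span_h) next
        if (max(y[i:j]) - min(y[i:j]) < log(min_fold)) next
        cand <- fit_window(i, j)
        if (cand$mu <= 0) next
        if (is.null(best) || cand$r2 > best$r2 + 1e-12 ||
            (abs(cand$r2 - best$r2) <= 1e-12 && cand$n > best$n))
          best <- cand
      }
    }
    if (is.null(best)) stopf("no exponential phase detected")
  }
  if (best$r2 < min_r_squared)
    stopf("no exponential phase detected (best r-squared %.3f < %.3f)",
          best$r2, min_r_squared)
  structure(list(mu = best$mu, doublings_per_hour = best$mu / log(2),
                 window = best$window, r_squared = best$r2,
                 n_points = best$n),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> mu = %.4f /h (%.3f doublings/h), window %g-%g h, r2 = %.4f (n = %d)\n",
              x$mu, x$doublings_per_hour, x$window[1], x$window[2],
              x$r_squared, x$n_points))
  invisible(x)
}

#' Regress specific growth rate on ammonification fraction
#'
#' Ordinary least squares of mu on f_amm across cultures, reporting the
#' slope, intercept, r-squared and the two-sided p-value for the slope.
#'
#' @param mu Specific growth rates, per hour.
#' @param f_amm Ammonification fractions in `[0, 1]`.
#' @return A `regression_result` list: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
growth_vs_partition_regression <- function(mu, f_amm) {
  if (length(mu) != length(f_amm)) stopf("mu and f_amm lengths differ")
  keep <- is.finite(mu) & is.finite(f_amm)
  mu <- mu[keep]; f_amm <- f_amm[keep]
  n <- length(mu)
  if (n < 3L) stopf("need at least 3 cultures")
  if (stats::var(f_amm) <= 0) stopf("degenerate regression: f_amm has no variance")
  fit <- stats::lm(mu ~ f_amm)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients["f_amm", "Pr(>|t|)"],
    n = n
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> mu = %.4f + %.4f * f_amm; R2 = %.3f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Full partition analysis of one culture's series
#'
#' Convenience wrapper: net changes over the window, N2O on the N basis,
#' pathway fractions, N recovery against nitrite consumed, and (when an
#' `od600` track is present) the growth fit.
#'
#' @param series A [metabolite_series()].
#' @param t_start,t_end Analysis window, hours.
#' @return List with `net_changes` (umol), `partition`, `recovery_percent`,
#'   `growth` (or NULL).
#' @export
analyze_culture <- function(series, t_start = min(series$time_h),
                            t_end = max(series$time_h)) {
  d_nh4 <- net_change(series, "ammonium", t_start, t_end)
  d_n2o_n <- n2o_to_nitrogen_basis(net_change(series, "n2o_umol", t_start, t_end))
  part <- withCallingHandlers(
    partition_pathways(d_nh4, d_n2o_n),
    warning = function(w) invokeRestart("muffleWarning"))
  d_no2 <- net_change(series, "nitrite", t_start, t_end)
  d_no3 <- net_change(series, "nitrate", t_start, t_end)
  # nitrite dissimilated = nitrite produced from nitrate minus nitrite left
  n_dissimilated <- -d_no3 - d_no2
  recovery <- if (is.finite(n_dissimilated) && n_dissimilated > 0)
    nitrogen_recovery(max(d_nh4, 0) + d_n2o_n, n_dissimilated) else NA_real_
  growth <- NULL
  if (!is.null(series$tracks$od600)) {
    growth <- tryCatch(
      fit_specific_growth_rate(series$time_h, series$tracks$od600),
      error = function(e) NULL)
  }
  list(net_changes = list(nh4_umol = d_nh4, n2o_n_umol = d_n2o_n,
                          nitrite_umol = d_no2, nitrate_umol = d_no3),
       partition = part, recovery_percent = recovery, growth = growth)
}
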