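.R_GAS <- 8.314462618e-3  # kJ/(mol K)

#' Two-state van't Hoff melting signal
#'
#' Equilibrium two-state unfolding with zero heat-capacity change:
#' K(T) = exp((dH / R) (1/Tm_K - 1/T_K)) with absolute temperatures,
#' fraction unfolded fU = K / (1 + K), and observed signal
#' (1 - fU) (native baseline at T) + fU (denatured baseline at T), both
#' baselines linear in temperature (degrees C).
#'
#' @param temp_C Temperature vector, degrees C.
#' @param tm Midpoint temperature, degrees C.
#' @param dH van't Hoff enthalpy at tm, kJ/mol (> 0 for an unfolding
#'   transition).
#' @param native,denatured Length-2 numeric: baseline intercept and slope.
#' @return Signal vector.
#' @export
two_state_signal <- function(temp_C, tm, dH, native = c(0, 0),
                             denatured = c(1, 0)) {
  fu <- fraction_unfolded(temp_C, tm, dH)
  (1 - fu) * (native[1] + native[2] * temp_C) +
    fu * (denatured[1] + denatured[2] * temp_C)
}

#' @rdname two_state_signal
#' @return `fraction_unfolded` returns fU in [0, 1].
#' @export
fraction_unfolded <- function(temp_C, tm, dH) {
  tk <- temp_C + 273.15
  tmk <- tm + 273.15
  lnK <- (dH / .R_GAS) * (1 / tmk - 1 / tk)
  1 / (1 + exp(-lnK))
}

.check_melting_curve <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("temp_C", "signal") %in% names(curve)))
  if (any(diff(curve$temp_C) <= 0))
    stop("temperatures must be strictly increasing")
  if (nrow(curve) < 10L) stop("too few points in melting curve")
  invisible(curve)
}

.smooth_ma <- function(x, window = 5L) {
  if (window < 2L) return(x)
  k <- rep(1 / window, window)
  as.numeric(stats::filter(x, k, sides = 2))
}

#' Locate the melting midpoint from the derivative of the melt
#'
#' Finite-difference derivative of the signal with respect to temperature,
#' smoothed with a centered moving average; the midpoint is the location of
#' the interior extremum of |dS/dT|, refined by parabolic interpolation of
#' the three points around the discrete peak. Works for both signal
#' directions.
#'
#' @param curve data.frame with `temp_C` and `signal` (>= 10 points).
#' @param window Smoothing window, points (default 5).
#' @return Midpoint temperature, degrees C.
#' @export
tm_from_derivative <- function(curve, window = 5L) {
  .check_melting_curve(curve)
  tmid <- (curve$temp_C[-1] + curve$temp_C[-nrow(curve)]) / 2
  # smooth the signed derivative first so zero-mean noise cancels
  d <- abs(.smooth_ma(diff(curve$signal) / diff(curve$temp_C), window))
  ok <- which(!is.na(d))
  if (!length(ok)) stop("curve too short for the smoothing window")
  d_ok <- d[ok]
  rng <- max(d_ok) - min(d_ok)
  if (rng <= 1e-8 * max(abs(d_ok), 1e-12))
    stop("no transition found: derivative has no interior extremum")
  i <- ok[which.max(d_ok)]
  if (i <= min(ok) || i >= max(ok))
    stop("no interior extremum: transition at the scan boundary")
  # parabolic refinement on the derivative peak
  y0 <- d[i - 1L]; y1 <- d[i]; y2 <- d[i + 1L]
  denom <- (y0 - 2 * y1 + y2)
  shift <- if (is.na(denom) || abs(denom) < 1e-15) 0 else
    0.5 * (y0 - y2) / denom
  shift <- max(-1, min(1, shift))
  h <- tmid[i + 1L] - tmid[i]
  tm <- tmid[i] + shift * h
  unname(tm)
}

#' Fit the two-state van't Hoff model to a melting curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) over six parameters:
#' tm, dH, and the two linear baselines. Initialization: tm from the
#' derivative peak, baselines from straight-line fits of the outer 20% of
#' points at each end, dH from the height of the normalized derivative peak
#' (dfU/dT at tm equals dH / (4 R Tm_K^2)). Requires the curve to span both
#' baselines: at least `min_flank` points on each side of the inflection and
#' a derivative that has decayed below 25% of its peak at both scan ends.
#'
#' @param curve data.frame `temp_C,signal` (optionally `channel`).
#' @param init Optional named list overriding starting values
#'   (`tm`, `dH`, `native`, `denatured`).
#' @param min_flank Minimum points required on each side of the inflection
#'   (default 5).
#' @return A `two_state_fit`: list with `tm`, `dH`, `native`, `denatured`,
#'   standard errors (`se`), `residual_sd`, `channel`, and the underlying
#'   `nls` fit object.
#' @export
fit_two_state <- function(curve, init = NULL, min_flank = 5L) {
  .check_melting_curve(curve)
  temp <- curve$temp_C; sig <- curve$signal
  n <- length(temp)
  tm0 <- tryCatch(tm_from_derivative(curve),
                  error = function(e) stop("cannot initialize fit: ",
                                           conditionMessage(e)))
  if (sum(temp < tm0) < min_flank || sum(temp > tm0) < min_flank)
    stop("curve does not span both baselines: fewer than ", min_flank,
         " points on one side of the inflection at ", round(tm0, 2), " C")
  # truncation check: heavily smoothed derivative must have decayed at both
  # scan ends (median of the outer points, robust to point noise)
  d <- diff(sig) / diff(temp)
  w <- max(7L, 2L * (length(d) %/% 20L) + 1L)
  ds <- abs(.smooth_ma(d, w))
  ds_ok <- ds[!is.na(ds)]
  m <- min(5L, length(ds_ok) %/% 3L)
  edge <- max(stats::median(ds_ok[seq_len(m)]),
              stats::median(ds_ok[length(ds_ok) - seq_len(m) + 1L]))
  if (edge > 0.3 * max(ds_ok))
    stop("curve truncated mid-transition: derivative still ",
         round(100 * edge / max(ds_ok)), "% of peak at a scan end")

  k <- max(min_flank, ceiling(0.2 * n))
  lo <- seq_len(k); hi <- seq(n - k + 1L, n)
  cf_n <- stats::coef(stats::lm(sig[lo] ~ temp[lo]))
  cf_d <- stats::coef(stats::lm(sig[hi] ~ temp[hi]))
  # dH from normalized derivative peak height
  amp <- (cf_d[1] + cf_d[2] * tm0) - (cf_n[1] + cf_n[2] * tm0)
  dH0 <- 300
  if (abs(amp) > 1e-12) {
    dfu <- (max(ds_ok) - mean(c(abs(cf_n[2]), abs(cf_d[2])))) / abs(amp)
    dH0 <- 4 * .R_GAS * (tm0 + 273.15)^2 * dfu
  }
  dH0 <- min(1500, max(50, dH0))
  start <- list(tm = tm0, dH = dH0,
                an = unname(cf_n[1]), bn = unname(cf_n[2]),
                ad = unname(cf_d[1]), bd = unname(cf_d[2]))
  if (!is.null(init)) {
    if (!is.null(init$tm)) start$tm <- init$tm
    if (!is.null(init$dH)) start$dH <- init$dH
    if (!is.null(init$native)) { start$an <- init$native[1]; start$bn <- init$native[2] }
    if (!is.null(init$denatured)) { start$ad <- init$denatured[1]; start$bd <- init$denatured[2] }
  }
  df <- data.frame(temp = temp, sig = sig)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      sig ~ two_state_signal(temp, tm, dH, c(an, bn), c(ad, bd)),
      data = df, start = start,
      lower = c(tm = min(temp), dH = 1, an = -Inf, bn = -Inf,
                ad = -Inf, bd = -Inf),
      upper = c(tm = max(temp), dH = Inf, an = Inf, bn = Inf,
                ad = Inf, bd = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop("two-state fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  if (cf[["dH"]] <= 0) stop("fitted dH non-positive: not a two-state melt")
  at_bound <- min(abs(cf[["tm"]] - range(temp)))
  if (at_bound < 1e-6)
    stop("fitted tm at the scan boundary; residual sd = ",
         signif(stats::sigma(fit), 4))
  structure(list(
    tm = unname(cf[["tm"]]), dH = unname(cf[["dH"]]),
    native = unname(c(cf[["an"]], cf[["bn"]])),
    denatured = unname(c(cf[["ad"]], cf[["bd"]])),
    se = se, residual_sd = stats::sigma(fit),
    tm_derivative = tm0,
    channel = if ("channel" %in% names(curve)) curve$channel[1L] else NA_character_,
    fit = fit), class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("Two-state melt fit: Tm = %.2f +/- %.2f C, dH(vH) = %.0f kJ/mol\n",
              x$tm, x$se[["tm"]], x$dH))
  cat(sprintf("  derivative-peak Tm = %.2f C, residual sd = %.3g, channel = %s\n",
              x$tm_derivative, x$residual_sd, x$channel))
  invisible(x)
}

#' Melting-temperature shift between two fits
#'
#' @param fit_a,fit_b `two_state_fit` objects from the same channel
#'   (reference first: the shift is `tm_b - tm_a`).
#' @return List with `delta_tm` (degrees C) and `se` (standard error,
#'   quadrature of the two tm errors).
#' @export
delta_tm <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "two_state_fit"), inherits(fit_b, "two_state_fit"))
  if (!is.na(fit_a$channel) && !is.na(fit_b$channel) &&
      fit_a$channel != fit_b$channel)
    stop("channel mismatch: ", fit_a$channel, " vs ", fit_b$channel)
  list(delta_tm = fit_b$tm - fit_a$tm,
       se = sqrt(fit_a$se[["tm"]]^2 + fit_b$se[["tm"]]^2))
}

#' Read / write melting-curve CSV (`temp_C,signal,channel`)
#' @param path File path.
#' @param curve data.frame to write.
#' @return `read_melting_csv` returns the data.frame.
#' @export
read_melting_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("temp_C", "signal") %in% names(x)))
  x
}

#' @rdname read_melting_csv
#' @export
write_melting_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
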