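#' Fit the linear conductivity-to-molarity gradient calibration
#'
#' On a heparin column run with a linear NaCl gradient, conductivity is
#' directly proportional to salt molarity; ordinary least squares of
#' conductivity on molarity gives the calibration line used to convert
#' elution-peak conductivities to [NaCl].
#'
#' @param conductivity Conductivity readings, mS/cm.
#' @param molarity Matching NaCl molarities, M.
#' @return A `gradient_calibration`: list with `slope` ((mS/cm)/M),
#'   `intercept` (mS/cm), `r_squared`, `n`.
#' @export
fit_calibration <- function(conductivity, molarity) {
  stopifnot(length(conductivity) == length(molarity))
  if (length(unique(molarity)) < 2L)
    stop("calibration needs >= 2 distinct molarity values")
  fit <- stats::lm(conductivity ~ molarity)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive; check axis order")
  r2 <- if (length(conductivity) > 2L) summary(fit)$r.squared else 1
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n = length(conductivity)),
            class = "gradient_calibration")
}

#' Convenience constructor for a known calibration line
#' @param slope,intercept Line parameters ((mS/cm)/M, mS/cm); slope > 0.
#' @return A `gradient_calibration`.
#' @export
gradient_calibration <- function(slope, intercept) {
  if (slope <= 0) stop("calibration slope must be positive")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = NA_real_, n = 0L),
            class = "gradient_calibration")
}

#' Convert conductivity to NaCl molarity under a calibration
#'
#' @param conductivity Conductivity, mS/cm.
#' @param calibration A `gradient_calibration`.
#' @param gradient Gradient range in M used for the out-of-range warning
#'   flag (default 0.5-2).
#' @return Molarity vector (attribute `"out_of_range"` flags values
#'   outside the gradient; a warning is raised but the value is returned).
#' @export
conductivity_to_nacl <- function(conductivity, calibration,
                                 gradient = c(0.5, 2.0)) {
  stopifnot(inherits(calibration, "gradient_calibration"))
  m <- (conductivity - calibration$intercept) / calibration$slope
  oor <- m < gradient[1L] | m > gradient[2L]
  if (any(oor))
    warning("converted molarity outside the ", gradient[1L], "-",
            gradient[2L], " M gradient")
  attr(m, "out_of_range") <- oor
  m
}

#' @rdname conductivity_to_nacl
#' @export
nacl_to_conductivity <- function(molarity, calibration) {
  stopifnot(inherits(calibration, "gradient_calibration"))
  calibration$intercept + calibration$slope * molarity
}

#' Locate the elution peak of an absorbance profile
#'
#' The discrete A280 maximum must be interior; its position is refined by
#' three-point parabolic interpolation (the convention of chromatography
#' software for near-symmetric peaks) on the volume axis, then read out as
#' conductivity (linear interpolation of the gradient trace) and converted
#' to [NaCl]. If a second local maximum exceeds half the global peak a
#' multi-peak warning is raised and the global maximum is reported.
#'
#' @param profile data.frame `volume_mL,conductivity_mS_cm,a280` (or
#'   `conductivity_mS_cm,a280` only, in which case conductivity is the
#'   abscissa).
#' @param calibration A `gradient_calibration`.
#' @return List with `peak_conductivity` (mS/cm) and `peak_nacl` (M).
#' @export
elution_peak <- function(profile, calibration) {
  stopifnot(is.data.frame(profile),
            all(c("conductivity_mS_cm", "a280") %in% names(profile)))
  x <- if ("volume_mL" %in% names(profile)) profile$volume_mL else
    profile$conductivity_mS_cm
  if (any(diff(x) <= 0)) stop("profile abscissa must be strictly increasing")
  y <- profile$a280
  n <- length(y)
  if (n < 3L) stop("profile too short")
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1))
    stop("flat profile: no elution peak")
  i <- which.max(y)
  if (i == 1L || i == n)
    stop("absorbance maximum at the profile boundary: no interior peak")
  if (diff(range(y[max(1, i - 1):min(n, i + 1)])) == 0 &&
      stats::var(y) == 0)
    stop("flat profile: no elution peak")
  # multi-peak scan on a smoothed trace: a secondary local maximum above
  # half height, outside the main peak's contiguous half-height region
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  half <- ys >= 0.5 * max(ys)
  main <- i
  lo <- main; while (lo > 1L && half[lo - 1L]) lo <- lo - 1L
  hi <- main; while (hi < n && half[hi + 1L]) hi <- hi + 1L
  interior <- which(diff(sign(diff(ys))) < 0) + 1L
  big <- interior[half[interior] & (interior < lo | interior > hi)]
  if (length(big) > 0L)
    warning("multiple elution peaks detected; reporting the global maximum")
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- y0 - 2 * y1 + y2
  shift <- if (abs(denom) < 1e-15) 0 else 0.5 * (y0 - y2) / denom
  shift <- max(-1, min(1, shift))
  x_peak <- x[i] + shift * (x[min(n, i + 1L)] - x[i])
  cond <- if ("volume_mL" %in% names(profile)) {
    stats::approx(profile$volume_mL, profile$conductivity_mS_cm,
                  xout = x_peak)$y
  } else x_peak
  list(peak_conductivity = cond,
       peak_nacl = as.numeric(conductivity_to_nacl(cond, calibration)))
}

#' Read / write elution CSV (`volume_mL,conductivity_mS_cm,a280`)
#' @param path File path.
#' @param profile data.frame to write.
#' @return `read_elution_csv` returns the data.frame.
#' @export
read_elution_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("conductivity_mS_cm", "a280") %in% names(x)))
  x
}

#' @rdname read_elution_csv
#' @export
write_elution_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
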