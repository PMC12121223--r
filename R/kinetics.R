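#' Sensorgram binding models (1:1 Langmuir and heterogeneous two-site)
#'
#' Pseudo-first-order kinetics of analyte at concentration C binding one or
#' two independent ligand-site populations. Association:
#' R(t) = sum_i Rmax_i C / (C + KD_i) (1 - exp(-(kon_i C + koff_i) t));
#' dissociation: each site decays exponentially with its own koff from its
#' response at the end of association.
#'
#' @param t Time vector, seconds, measured from the start of the given
#'   phase.
#' @param phase "association" or "dissociation".
#' @param kon,koff,rmax Per-site parameter vectors (length 1 or 2);
#'   kon in 1/(uM s), koff in 1/s, rmax in sensor units.
#' @param C Analyte concentration, uM (required for association and to set
#'   the dissociation starting level).
#' @param t_assoc Association duration, s (needed for the dissociation
#'   starting level; default 450).
#' @return Response vector.
#' @export
model_response <- function(t, phase = c("association", "dissociation"),
                           kon, koff, rmax, C, t_assoc = 450) {
  phase <- match.arg(phase)
  stopifnot(length(koff) == length(kon), length(rmax) == length(kon))
  if (phase == "association" && (length(C) != 1L || C <= 0))
    stop("association requires a single positive concentration")
  r <- rep(0, length(t))
  for (i in seq_along(kon)) {
    req <- rmax[i] * C / (C + koff[i] / kon[i])
    if (phase == "association") {
      r <- r + req * (1 - exp(-(kon[i] * C + koff[i]) * t))
    } else {
      r_end <- req * (1 - exp(-(kon[i] * C + koff[i]) * t_assoc))
      r <- r + r_end * exp(-koff[i] * t)
    }
  }
  r
}

#' Equilibrium dissociation constant from rate constants
#' @param kon Association rate constant, 1/(uM s).
#' @param koff Dissociation rate constant, 1/s.
#' @return KD = koff / kon, uM.
#' @export
kd_from_rates <- function(kon, koff) {
  if (any(kon <= 0) || any(koff <= 0)) stop("rates must be > 0")
  koff / kon
}

#' Affinity fold-change between two dissociation constants
#'
#' Ratio `kd_ref / kd_new`: values above 1 mean the new molecule binds
#' tighter than the reference.
#' @param kd_ref,kd_new Dissociation constants, same units (> 0).
#' @return Dimensionless fold change.
#' @export
fold_change <- function(kd_ref, kd_new) {
  if (any(kd_ref <= 0) || any(kd_new <= 0)) stop("KD values must be > 0")
  kd_ref / kd_new
}

.check_sensorgrams <- function(sg) {
  stopifnot(is.data.frame(sg),
            all(c("time_s", "response", "conc_uM", "phase") %in% names(sg)))
  if (!all(sg$phase %in% c("association", "dissociation")))
    stop("phase must be association/dissociation")
  if (any(sg$conc_uM <= 0)) stop("concentrations must be > 0")
  invisible(sg)
}

# initial estimates: koff from the log-linear dissociation tail, kon from
# the k_obs-vs-concentration regression
.kinetics_init <- function(sg) {
  concs <- sort(unique(sg$conc_uM))
  t_assoc <- max(sg$time_s[sg$phase == "association"])
  dis <- sg[sg$phase == "dissociation", ]
  koff0 <- 0.1
  d1 <- dis[dis$conc_uM == concs[length(concs)], ]
  pos <- d1$response > max(d1$response, 0) * 0.02 & d1$response > 0
  if (sum(pos) > 5) {
    cf <- stats::coef(stats::lm(log(d1$response[pos]) ~ d1$time_s[pos]))
    if (is.finite(cf[2]) && cf[2] < 0) koff0 <- -unname(cf[2])
  }
  kobs <- vapply(concs, function(C) {
    a <- sg[sg$phase == "association" & sg$conc_uM == C, ]
    amax <- max(a$response)
    if (amax <= 0) return(NA_real_)
    i63 <- which(a$response >= 0.632 * amax)[1L]
    if (is.na(i63) || a$time_s[i63] <= 0) return(NA_real_)
    1 / a$time_s[i63]
  }, numeric(1))
  ok <- is.finite(kobs)
  kon0 <- 0.5
  if (sum(ok) >= 2) {
    cf <- stats::coef(stats::lm(kobs[ok] ~ concs[ok]))
    if (is.finite(cf[2]) && cf[2] > 0) kon0 <- unname(cf[2])
  }
  kd0 <- koff0 / kon0
  cmax <- concs[length(concs)]
  amax <- max(sg$response[sg$phase == "association" & sg$conc_uM == cmax])
  rmax0 <- amax / (cmax / (cmax + kd0))
  if (!is.finite(rmax0) || rmax0 <= 0) rmax0 <- max(sg$response)
  list(kon = kon0, koff = koff0, rmax = rmax0, t_assoc = t_assoc)
}

#' Global fit of multi-concentration sensorgrams
#'
#' Least-squares fit of [model_response()] jointly across all
#' concentrations and both phases. Rate constants are global; per-site rmax
#' is shared across concentrations. With `n_sites = 2` this is the
#' heterogeneous-ligand (two independent 1:1 site populations) model; the
#' reported KD is koff/kon of the dominant (larger-rmax) site, with both
#' sites retained in the output. Inputs are assumed reference-subtracted.
#'
#' @param sensorgrams data.frame `time_s,response,conc_uM,phase` with at
#'   least two concentrations.
#' @param n_sites 1 or 2.
#' @param init Optional named list (`kon`, `koff`, `rmax`; vectors of
#'   length `n_sites`) overriding automatic initialization.
#' @return A `kinetics_fit`: list with per-site `kon`, `koff`, `rmax`,
#'   their standard errors (`kon_se`, ...), `n_sites`, `reported_site`,
#'   `kd_reported`, `kd_se`, `residual_sd`, and the underlying `nls` fit.
#' @export
global_fit <- function(sensorgrams, n_sites = 1L, init = NULL) {
  .check_sensorgrams(sensorgrams)
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites %in% c(1L, 2L))
  if (length(unique(sensorgrams$conc_uM)) < 2L)
    stop("global fit requires >= 2 analyte concentrations")
  sg <- sensorgrams
  t_assoc <- max(sg$time_s[sg$phase == "association"])
  sg$t_phase <- ifelse(sg$phase == "association", sg$time_s,
                       sg$time_s - t_assoc)
  ini <- .kinetics_init(sg)
  if (n_sites == 1L) {
    start <- list(k1 = ini$kon, d1 = ini$koff, r1 = ini$rmax)
  } else {
    start <- list(k1 = ini$kon, d1 = ini$koff, r1 = 0.6 * ini$rmax,
                  k2 = ini$kon / 8, d2 = ini$koff * 8, r2 = 0.4 * ini$rmax)
  }
  if (!is.null(init)) {
    if (!is.null(init$kon)) { start$k1 <- init$kon[1]; if (n_sites == 2) start$k2 <- init$kon[2] }
    if (!is.null(init$koff)) { start$d1 <- init$koff[1]; if (n_sites == 2) start$d2 <- init$koff[2] }
    if (!is.null(init$rmax)) { start$r1 <- init$rmax[1]; if (n_sites == 2) start$r2 <- init$rmax[2] }
  }
  pred <- function(pars) {
    kon <- c(pars[["k1"]], if (n_sites == 2) pars[["k2"]])
    koff <- c(pars[["d1"]], if (n_sites == 2) pars[["d2"]])
    rmax <- c(pars[["r1"]], if (n_sites == 2) pars[["r2"]])
    out <- numeric(nrow(sg))
    for (C in unique(sg$conc_uM)) {
      ia <- sg$conc_uM == C & sg$phase == "association"
      id <- sg$conc_uM == C & sg$phase == "dissociation"
      out[ia] <- model_response(sg$t_phase[ia], "association",
                                kon, koff, rmax, C, t_assoc)
      out[id] <- model_response(sg$t_phase[id], "dissociation",
                                kon, koff, rmax, C, t_assoc)
    }
    out
  }
  pred_sensorgram <- function(...) {
    p <- list(...)
    names(p) <- names(start)
    pred(p)
  }
  form <- if (n_sites == 1L)
    response ~ pred_sensorgram(k1, d1, r1) else
    response ~ pred_sensorgram(k1, d1, r1, k2, d2, r2)
  dat <- sg["response"]
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      lower = rep(1e-8, length(start)),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) stop("global kinetic fit failed to converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (any(cf <= 1.5e-8))
    stop("kinetic fit collapsed: a rate or rmax hit its lower bound")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  kon <- unname(cf[grep("^k", names(cf))])
  koff <- unname(cf[grep("^d", names(cf))])
  rmax <- unname(cf[grep("^r", names(cf))])
  rep_site <- which.max(rmax)
  kd <- kd_from_rates(kon[rep_site], koff[rep_site])
  kon_se <- unname(se[grep("^k", names(cf))])
  koff_se <- unname(se[grep("^d", names(cf))])
  kd_se <- kd * sqrt((kon_se[rep_site] / kon[rep_site])^2 +
                       (koff_se[rep_site] / koff[rep_site])^2)
  structure(list(
    kon = kon, koff = koff, rmax = rmax,
    kon_se = kon_se, koff_se = koff_se,
    rmax_se = unname(se[grep("^r", names(cf))]),
    n_sites = n_sites, reported_site = rep_site,
    kd_reported = kd, kd_se = kd_se,
    residual_sd = stats::sigma(fit), fit = fit), class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  i <- x$reported_site
  cat(sprintf(
    "Kinetic fit (%d site%s): kon = %.3g 1/(uM s), koff = %.3g 1/s, KD = %.3g uM\n",
    x$n_sites, if (x$n_sites > 1) "s" else "", x$kon[i], x$koff[i],
    x$kd_reported))
  cat(sprintf("  residual sd = %.3g (reported site %d of %d)\n",
              x$residual_sd, i, x$n_sites))
  invisible(x)
}

#' Qualitative binding screen from single-concentration traces
#'
#' A ligand is called bound when the maximum association-phase response
#' exceeds `threshold` (reference-subtracted traces assumed).
#'
#' @param sensorgrams data.frame `time_s,response,conc_uM,phase`,
#'   optionally with a `ligand` column distinguishing traces.
#' @param threshold Response threshold, sensor units.
#' @return data.frame `ligand,max_response,bound`.
#' @export
binding_screen <- function(sensorgrams, threshold) {
  .check_sensorgrams(sensorgrams)
  sg <- sensorgrams
  if (!"ligand" %in% names(sg)) sg$ligand <- "ligand"
  a <- sg[sg$phase == "association", ]
  mx <- tapply(a$response, a$ligand, max)
  data.frame(ligand = names(mx), max_response = as.numeric(mx),
             bound = as.numeric(mx) > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Subtract a paired reference sensorgram
#'
#' @param sensorgrams,reference data.frames with matching
#'   `time_s,conc_uM,phase` grids.
#' @return `sensorgrams` with the reference response subtracted.
#' @export
subtract_reference <- function(sensorgrams, reference) {
  .check_sensorgrams(sensorgrams)
  key <- function(d) paste(d$time_s, d$conc_uM, d$phase)
  i <- match(key(sensorgrams), key(reference))
  if (anyNA(i)) stop("reference trace does not cover all sample points")
  out <- sensorgrams
  out$response <- out$response - reference$response[i]
  out
}

#' Read / write sensorgram CSV (`time_s,response,conc_uM,phase`)
#' @param path File path.
#' @param sensorgrams data.frame to write.
#' @return `read_sensorgram_csv` returns the data.frame.
#' @export
read_sensorgram_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_sensorgrams(x)
  x
}

#' @rdname read_sensorgram_csv
#' @export
write_sensorgram_csv <- function(sensorgrams, path) {
  utils::write.csv(sensorgrams, path, row.names = FALSE)
  invisible(path)
}
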