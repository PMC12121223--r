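#' Specification for synthetic instrument data
#'
#' Bundles the random seed, the noise level and the sampling grids used by
#' every generator. Identical specs give bit-identical output; the global
#' RNG state is saved and restored around every draw, so generators have no
#' hidden side effects.
#'
#' @param seed Integer random seed.
#' @param noise_sd Gaussian noise standard deviation in signal units.
#'   `NULL` (default) means 1% of the noiseless curve's dynamic range; 0
#'   gives noiseless curves.
#' @param dt_s Sensorgram sampling interval, seconds (default 0.5, i.e.
#'   2 Hz).
#' @param dT_C Melting-curve temperature step, degrees C (default 0.5).
#' @param dv_mL Elution-profile volume step, mL (default 0.05).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, noise_sd = NULL, dt_s = 0.5,
                           dT_C = 0.5, dv_mL = 0.05) {
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(dt_s > 0, dT_C > 0, dv_mL > 0)
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 dt_s = dt_s, dT_C = dT_C, dv_mL = dv_mL),
            class = "synthetic_spec")
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.noise_for <- function(signal, spec) {
  sd <- spec$noise_sd
  if (is.null(sd)) sd <- 0.01 * diff(range(signal))
  if (sd == 0) return(rep(0, length(signal)))
  .with_seed(spec$seed, stats::rnorm(length(signal), 0, sd))
}

#' Generate a toy ligand-bound protein structure with known geometry
#'
#' Residues are laid on a regular extended backbone along x (3.8 Angstrom
#' spacing) with CB pointing along +z. A rigid multi-atom pseudo-ligand
#' (residue name `LIG`) is placed so that each residue in `near_positions`
#' has minimum heavy-atom distance to the ligand exactly equal to
#' `ligand_offset` (anchored at its CB). Residues in `clash_positions` get
#' a blocker atom (chain X, residue `BLK`) placed 3 Angstrom above CB, in
#' the path of any side chain extended by [mutate_residue()], guaranteeing
#' a clash at the default 2.4-Angstrom cutoff without clashing against the
#' unmutated residue.
#'
#' @param n_residues Number of protein residues (>= 3).
#' @param ligand_offset Ligand placement distance, Angstrom (> 0).
#' @param clash_positions Residue numbers that must clash upon side-chain
#'   extension.
#' @param seed Integer seed (the geometry is fully deterministic; the seed
#'   is part of the spec for interface uniformity).
#' @param sequence Optional 1-letter protein sequence of length
#'   `n_residues` used for residue names (default poly-Ala).
#' @param near_positions Residues anchored at `ligand_offset` from the
#'   ligand; default the middle residue.
#' @return A `fgf_structure`; attribute `"near_positions"` records the
#'   anchored residues.
#' @export
make_toy_complex <- function(n_residues, ligand_offset = 5,
                             clash_positions = integer(0), seed = 1L,
                             sequence = NULL, near_positions = NULL) {
  if (n_residues < 3L) stop("n_residues must be >= 3")
  if (ligand_offset <= 0) stop("ligand_offset must be > 0")
  clash_positions <- as.integer(clash_positions)
  if (length(clash_positions) &&
      (min(clash_positions) < 1L || max(clash_positions) > n_residues))
    stop("clash_positions outside 1..n_residues")
  if (is.null(near_positions)) near_positions <- as.integer(ceiling(n_residues / 2))
  near_positions <- sort(unique(as.integer(near_positions)))
  if (min(near_positions) < 1L || max(near_positions) > n_residues)
    stop("near_positions outside 1..n_residues")
  if (is.null(sequence)) sequence <- strrep("A", n_residues)
  res1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(res1) != n_residues) stop("sequence length != n_residues")
  if (!all(res1 %in% names(.AA3))) stop("invalid residue letters in sequence")

  rows <- list()
  for (i in seq_len(n_residues)) {
    xc <- 3.8 * i
    at <- data.frame(
      atom = c("N", "CA", "C", "O"),
      x = c(xc - 1.2, xc, xc + 1.2, xc + 1.2),
      y = c(-0.8, 0, -0.8, -1.9),
      z = 0, stringsAsFactors = FALSE)
    if (res1[i] != "G") {
      at <- rbind(at, data.frame(atom = "CB", x = xc, y = 0, z = 1.53))
    }
    at$resname <- .AA3[[res1[i]]]; at$chain <- "A"; at$resno <- i
    at$is_ligand <- FALSE
    rows[[length(rows) + 1L]] <- at
  }
  # ligand: one anchor atom per near residue, padded to >= 5 atoms
  lig_x <- 3.8 * near_positions
  n_pad <- max(0L, 5L - length(lig_x))
  pad <- if (n_pad > 0) data.frame(
    atom = paste0("C", length(lig_x) + seq_len(n_pad)),
    x = 3.8 * near_positions[1L] + 1.5 * seq_len(n_pad),
    y = ligand_offset + 2.0, z = 1.53, stringsAsFactors = FALSE)
  lig <- rbind(
    data.frame(atom = paste0("C", seq_along(lig_x)), x = lig_x,
               y = ligand_offset, z = 1.53, stringsAsFactors = FALSE),
    pad)
  lig$resname <- "LIG"; lig$chain <- "L"; lig$resno <- 1L
  lig$is_ligand <- TRUE
  rows[[length(rows) + 1L]] <- lig
  if (length(clash_positions)) {
    blk <- data.frame(
      atom = paste0("BK", seq_along(clash_positions)),
      x = 3.8 * clash_positions, y = 0, z = 1.53 + 3.0,
      resname = "BLK", chain = "X",
      resno = 900L + clash_positions, is_ligand = FALSE,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- blk
  }
  df <- do.call(rbind, rows)
  df$element <- .element_of(df$atom)
  df$element[df$atom %in% paste0("BK", seq_len(99))] <- "C"
  df$eleno <- seq_len(nrow(df))
  df$x <- round(df$x, 3); df$y <- round(df$y, 3); df$z <- round(df$z, 3)
  st <- .new_structure(df)
  attr(st, "near_positions") <- near_positions
  st
}

#' Generate a toy alignment with planted basic-residue support
#'
#' Builds an aligned set of sequences around a fixed target row. For every
#' column named in `support_map`, exactly that many non-target rows carry
#' Lys or Arg; all remaining non-target cells are drawn from non-basic
#' residues. This gives column-level ground truth for the candidate-column
#' rule.
#'
#' @param target_row Target (ungapped) sequence; becomes row `target_id`.
#' @param support_map Named integer vector: names are column indices,
#'   values the required K/R count among non-target rows (each must be
#'   <= n_rows - 1). Unlisted columns get support 0.
#' @param n_rows Total number of rows including the target.
#' @param seed Integer seed.
#' @param target_id Row id of the target (default "FGF1").
#' @return Named character vector (alignment), with attribute
#'   `"support_map"` giving the planted support for every column.
#' @export
make_toy_alignment <- function(target_row, support_map = integer(0),
                               n_rows = 6L, seed = 1L,
                               target_id = "FGF1") {
  stopifnot(is.character(target_row), length(target_row) == 1L, n_rows >= 2L)
  width <- nchar(target_row)
  sm <- integer(width)
  if (length(support_map)) {
    cols <- as.integer(names(support_map))
    if (anyNA(cols) || any(cols < 1L | cols > width))
      stop("support_map columns outside alignment width")
    if (any(support_map > n_rows - 1L))
      stop("impossible support count: exceeds n_rows - 1")
    sm[cols] <- as.integer(support_map)
  }
  nonbasic <- c("A", "S", "T", "D", "E", "G", "L", "V", "N", "Q", "F", "P")
  .with_seed(seed, {
    m <- matrix("", nrow = n_rows - 1L, ncol = width)
    for (j in seq_len(width)) {
      m[, j] <- sample(nonbasic, n_rows - 1L, replace = TRUE)
      if (sm[j] > 0L) {
        rows <- sample.int(n_rows - 1L, sm[j])
        m[rows, j] <- sample(c("K", "R"), sm[j], replace = TRUE)
      }
    }
    aln <- c(toupper(target_row),
             apply(m, 1L, paste, collapse = ""))
    names(aln) <- c(target_id, paste0("HOMOLOG", seq_len(n_rows - 1L)))
    attr(aln, "support_map") <- sm
    aln
  })
}

#' Simulate multi-concentration BLI sensorgrams
#'
#' Pseudo-first-order 1:1 binding per site: during association
#' R(t) = sum_i Req_i(C) (1 - exp(-(kon_i C + koff_i) t)) with
#' Req_i(C) = rmax_i C / (C + koff_i / kon_i); during dissociation each
#' site decays from its association end point as exp(-koff_i t'). Supplying
#' length-2 rate vectors gives heterogeneous two-site traces. Gaussian
#' noise of sd `spec$noise_sd` is added pointwise.
#'
#' @param kon Association rate constant(s), 1/(uM s).
#' @param koff Dissociation rate constant(s), 1/s.
#' @param rmax Maximal response(s), sensor units.
#' @param concentrations Analyte concentrations, uM (non-empty).
#' @param t_assoc,t_dissoc Phase durations, s (default 450 + 450).
#' @param spec A [synthetic_spec()].
#' @return data.frame `time_s,response,conc_uM,phase` (one block per
#'   concentration; `phase` is "association"/"dissociation").
#' @export
simulate_sensorgram <- function(kon, koff, rmax, concentrations,
                                t_assoc = 450, t_dissoc = 450,
                                spec = synthetic_spec()) {
  if (any(kon <= 0) || any(koff <= 0) || any(rmax <= 0))
    stop("rates and rmax must be > 0")
  if (!length(concentrations) || any(concentrations <= 0))
    stop("concentrations must be a non-empty positive vector")
  stopifnot(length(koff) == length(kon), length(rmax) == length(kon))
  dt <- spec$dt_s
  ta <- seq(0, t_assoc, by = dt)
  td <- seq(dt, t_dissoc, by = dt)
  out <- lapply(concentrations, function(C) {
    r_a <- rep(0, length(ta)); r_end <- numeric(length(kon))
    for (i in seq_along(kon)) {
      req <- rmax[i] * C / (C + koff[i] / kon[i])
      kobs <- kon[i] * C + koff[i]
      r_a <- r_a + req * (1 - exp(-kobs * ta))
      r_end[i] <- req * (1 - exp(-kobs * t_assoc))
    }
    r_d <- rep(0, length(td))
    for (i in seq_along(kon)) r_d <- r_d + r_end[i] * exp(-koff[i] * td)
    data.frame(
      time_s = c(ta, t_assoc + td),
      response = c(r_a, r_d),
      conc_uM = C,
      phase = rep(c("association", "dissociation"),
                  c(length(ta), length(td))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$response <- out$response + .noise_for(out$response, spec)
  out
}

#' Simulate a two-state thermal melting curve
#'
#' Samples the two-state van't Hoff signal model (see
#' [two_state_signal()]) on a 20-90 degree C grid with linear native and
#' denatured baselines and Gaussian noise.
#'
#' @param tm Midpoint temperature, degrees C (must lie in the 20-90 scan
#'   window).
#' @param dH van't Hoff enthalpy at tm, kJ/mol (> 0).
#' @param baselines Numeric length-4: native intercept, native slope,
#'   denatured intercept, denatured slope (signal units, per degree C).
#'   Defaults depend on `direction`.
#' @param direction "increasing" (unfolding raises the signal, e.g. Trp
#'   fluorescence at 353 nm) or "decreasing" (e.g. ellipticity loss).
#' @param channel Channel label ("FL_353nm" or "CD_228nm").
#' @param spec A [synthetic_spec()].
#' @return data.frame `temp_C,signal,channel`.
#' @export
simulate_melting_curve <- function(tm, dH, baselines = NULL,
                                   direction = c("increasing", "decreasing"),
                                   channel = NULL,
                                   spec = synthetic_spec()) {
  direction <- match.arg(direction)
  if (tm < 20 || tm > 90) stop("tm outside the 20-90 C scan window")
  if (dH <= 0) stop("dH must be > 0")
  if (is.null(baselines)) {
    baselines <- if (direction == "increasing")
      c(0.10, -0.0005, 1.00, -0.0020) else c(1.00, -0.0020, 0.10, -0.0005)
  }
  if (is.null(channel)) {
    channel <- if (direction == "increasing") "FL_353nm" else "CD_228nm"
  }
  stopifnot(length(baselines) == 4L)
  temp <- seq(20, 90, by = spec$dT_C)
  sig <- two_state_signal(temp, tm = tm, dH = dH,
                          native = baselines[1:2],
                          denatured = baselines[3:4])
  sig <- sig + .noise_for(sig, spec)
  data.frame(temp_C = temp, signal = sig, channel = channel,
             stringsAsFactors = FALSE)
}

#' Simulate a heparin-column elution profile
#'
#' Linear 0.5-2 M NaCl gradient over the run volume, conductivity obtained
#' from the supplied calibration, and a Gaussian A280 peak centered at the
#' volume whose gradient molarity equals `peak_nacl`.
#'
#' @param calibration A `gradient_calibration` (see [fit_calibration()]).
#' @param peak_nacl Elution-peak NaCl molarity, M (within 0.5-2).
#' @param spec A [synthetic_spec()].
#' @param total_volume_mL Gradient length, mL (default 30).
#' @param peak_width_mL Gaussian sigma of the peak, mL (default 0.8).
#' @param amplitude Peak A280 amplitude, mAU (default 100).
#' @return data.frame `volume_mL,conductivity_mS_cm,a280`.
#' @export
simulate_elution <- function(calibration, peak_nacl,
                             spec = synthetic_spec(),
                             total_volume_mL = 30, peak_width_mL = 0.8,
                             amplitude = 100) {
  stopifnot(inherits(calibration, "gradient_calibration"))
  if (peak_nacl < 0.5 || peak_nacl > 2.0)
    stop("peak_nacl outside the 0.5-2 M gradient")
  v <- seq(0, total_volume_mL, by = spec$dv_mL)
  molarity <- 0.5 + (2.0 - 0.5) * v / total_volume_mL
  cond <- calibration$intercept + calibration$slope * molarity
  v_peak <- total_volume_mL * (peak_nacl - 0.5) / 1.5
  a280 <- amplitude * exp(-(v - v_peak)^2 / (2 * peak_width_mL^2))
  a280 <- a280 + .noise_for(a280, spec)
  data.frame(volume_mL = v, conductivity_mS_cm = cond, a280 = a280)
}
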