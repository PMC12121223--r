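# Independent brute-force oracles and random-fixture generators used across
# the suite. Everything here is deliberately naive (double loops, per-column
# recounts) so it cannot share a bug with the vectorized implementation.

oracle_min_dist <- function(structure, position, chain = NULL) {
  res <- structure$resno == position & !structure$is_ligand
  if (!is.null(chain)) res <- res & structure$chain == chain
  lig <- structure$is_ligand
  best <- Inf
  for (i in which(res)) {
    for (j in which(lig)) {
      d <- sqrt((structure$x[i] - structure$x[j])^2 +
                  (structure$y[i] - structure$y[j])^2 +
                  (structure$z[i] - structure$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

oracle_clash <- function(structure, position, cutoff = 2.4) {
  bb <- c("N", "CA", "C", "O", "OXT")
  res <- which(structure$resno == position & !structure$is_ligand)
  ch <- structure$chain[res[1]]
  side <- res[!structure$atom[res] %in% bb]
  for (i in side) {
    for (j in seq_len(nrow(structure))) {
      if (j %in% res) next
      same_chain <- structure$chain[j] == ch && !structure$is_ligand[j]
      if (same_chain && abs(structure$resno[j] - position) == 1 &&
          structure$atom[j] %in% bb) next
      d <- sqrt((structure$x[i] - structure$x[j])^2 +
                  (structure$y[i] - structure$y[j])^2 +
                  (structure$z[i] - structure$z[j])^2)
      if (d < cutoff) return(TRUE)
    }
  }
  FALSE
}

# per-column recount of the conservation / support rules
oracle_classify <- function(alignment, target_id = NULL, min_count = 3) {
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(m) <- names(alignment)
  classes <- list(positive = c("K", "R", "H"), negative = c("D", "E"),
                  polar = c("S", "T", "N", "Q", "C", "Y", "W"),
                  nonpolar = c("A", "V", "L", "I", "M", "F", "P", "G"))
  cl_of <- function(a) {
    for (nm in names(classes)) if (a %in% classes[[nm]]) return(nm)
    NA_character_
  }
  out <- character(ncol(m)); sup <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[!col %in% c("-", ".")]
    ident <- FALSE
    for (a in unique(res)) if (sum(res == a) >= min_count) ident <- TRUE
    if (ident) out[j] <- "identical_conserved"
    else {
      cls <- vapply(res, cl_of, character(1))
      cls_hit <- FALSE
      for (cc in unique(cls[!is.na(cls)]))
        if (sum(cls == cc, na.rm = TRUE) >= min_count) cls_hit <- TRUE
      out[j] <- if (cls_hit) "class_conserved" else "unconserved"
    }
    others <- if (is.null(target_id)) col else
      col[setdiff(rownames(m), target_id)]
    sup[j] <- sum(others %in% c("K", "R"))
  }
  list(class = out, support = sup)
}

# random multi-residue structure with one ligand residue, for oracle checks
random_structure <- function(n_res, atoms_per_res = 4, n_lig = 5,
                             box = 25, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_res)) {
    k <- sample(2:atoms_per_res, 1) + 2
    nm <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE")[seq_len(k)]
    rows[[i]] <- data.frame(
      atom = nm, resname = "ALA", chain = "A", resno = i,
      x = runif(k, 0, box), y = runif(k, 0, box), z = runif(k, 0, box),
      is_ligand = FALSE, stringsAsFactors = FALSE)
  }
  rows[[n_res + 1]] <- data.frame(
    atom = paste0("C", seq_len(n_lig)), resname = "LIG", chain = "L",
    resno = 1, x = runif(n_lig, 0, box), y = runif(n_lig, 0, box),
    z = runif(n_lig, 0, box), is_ligand = TRUE, stringsAsFactors = FALSE)
  df <- do.call(rbind, rows)
  df$element <- substr(df$atom, 1, 1)
  df$eleno <- seq_len(nrow(df))
  df$x <- round(df$x, 3); df$y <- round(df$y, 3); df$z <- round(df$z, 3)
  class(df) <- c("fgf_structure", "data.frame")
  df
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_out)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_structure <- function(structure, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(R)
  out <- structure
  out$x <- xyz[, 1] + shift[1]
  out$y <- xyz[, 2] + shift[2]
  out$z <- xyz[, 3] + shift[3]
  out
}
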