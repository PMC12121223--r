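#' Ligand residue names recognized by default
#'
#' Common PDB chemical-component codes for heparin/heparan-sulfate sugar
#' units, plus the pseudo-ligand code (`LIG`) used by the synthetic toy
#' complexes.
#' @return Character vector of residue names.
#' @export
default_ligand_names <- function() {
  c("SGN", "IDS", "IDU", "UAP", "BDP", "GCU", "HEP", "LIG")
}

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.AA1 <- stats::setNames(names(.AA3), .AA3)

# Heavy side-chain atoms beyond CB, in chain order used for the idealized
# collinear extension.
.SIDECHAIN_BEYOND_CB <- list(
  ALA = character(0), GLY = character(0),
  SER = "OG", CYS = "SG", PRO = c("CG", "CD"),
  THR = c("OG1", "CG2"), VAL = c("CG1", "CG2"),
  LEU = c("CG", "CD1", "CD2"), ILE = c("CG1", "CG2", "CD1"),
  MET = c("CG", "SD", "CE"),
  ASP = c("CG", "OD1", "OD2"), ASN = c("CG", "OD1", "ND2"),
  GLU = c("CG", "CD", "OE1", "OE2"), GLN = c("CG", "CD", "OE1", "NE2"),
  LYS = c("CG", "CD", "CE", "NZ"),
  ARG = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

.BACKBONE <- c("N", "CA", "C", "O", "OXT")
.CC_BOND <- 1.53  # standard heavy-atom bond length, Angstrom

.element_of <- function(atom_name) {
  a <- gsub("[^A-Za-z]", "", atom_name)
  substr(a, 1L, 1L)
}

.new_structure <- function(df) {
  need <- c("eleno", "atom", "resname", "chain", "resno",
            "x", "y", "z", "element", "is_ligand")
  stopifnot(all(need %in% names(df)))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite atom coordinates")
  key <- paste(df$chain, df$resno, df$atom)
  if (anyDuplicated(key)) stop("duplicate (chain, residue, atom name)")
  df <- df[, need]
  rownames(df) <- NULL
  class(df) <- c("fgf_structure", "data.frame")
  df
}

#' Read a protein(-ligand) structure from PDB text or file
#'
#' Parses ATOM/HETATM records (via bio3d). HETATM residues whose name is in
#' `ligand_names` are flagged `is_ligand`; waters are dropped; hydrogens are
#' dropped (all geometry here is heavy-atom). Coordinate fields are
#' pre-validated so a malformed record reports its line number.
#'
#' @param x Path to a PDB file, or PDB-format text (single string or
#'   character vector of lines).
#' @param ligand_names Residue names treated as ligand, see
#'   [default_ligand_names()].
#' @return A `fgf_structure`: data.frame with columns `eleno`, `atom`,
#'   `resname`, `chain`, `resno`, `x`, `y`, `z`, `element`, `is_ligand`.
#' @export
read_structure <- function(x, ligand_names = default_ligand_names()) {
  is_path <- length(x) == 1L && !grepl("\n", x) && file.exists(x)
  lines <- if (is_path) readLines(x, warn = FALSE) else
    unlist(strsplit(x, "\n", fixed = TRUE))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records found")
  for (i in which(rec)) {
    coords <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("malformed coordinate field at line ", i, ": ", lines[i])
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  a <- pdb$atom
  keep <- !(a$resid %in% c("HOH", "WAT", "DOD")) &
    !(toupper(a$elesy) %in% "H") & .element_of(a$elety) != "H"
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("structure contains only waters/hydrogens")
  elem <- ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                 .element_of(a$elety), trimws(a$elesy))
  st <- .new_structure(data.frame(
    eleno = a$eleno, atom = trimws(a$elety), resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain),
    resno = a$resno, x = a$x, y = a$y, z = a$z,
    element = elem, is_ligand = trimws(a$resid) %in% ligand_names,
    stringsAsFactors = FALSE))
  st
}

#' Write a structure as a PDB file
#'
#' @param structure A `fgf_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  s <- structure
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    type = ifelse(s$is_ligand, "HETATM", "ATOM"),
    resno = s$resno, resid = s$resname, eleno = s$eleno,
    elety = s$atom, chain = s$chain, o = rep(1, nrow(s)),
    b = rep(0, nrow(s)), elesy = s$element)
  invisible(path)
}

.residue_rows <- function(structure, position, chain = NULL) {
  hit <- structure$resno == position & !structure$is_ligand
  if (!is.null(chain)) hit <- hit & structure$chain == chain
  if (!any(hit)) stop("residue ", position,
                      if (!is.null(chain)) paste0(" (chain ", chain, ")"),
                      " not found in structure")
  which(hit)
}

.pairwise_min_dist <- function(A, B) {
  # A, B: n x 3 matrices; minimum Euclidean distance over all pairs
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Minimum heavy-atom distance from a residue to the ligand
#'
#' @param structure A `fgf_structure` containing at least one ligand atom.
#' @param position Residue number.
#' @param chain Optional chain id restricting the residue lookup.
#' @return Distance in Angstrom.
#' @export
min_distance_to_ligand <- function(structure, position, chain = NULL) {
  lig <- which(structure$is_ligand)
  if (!length(lig)) stop("structure has no ligand atoms")
  res <- .residue_rows(structure, position, chain)
  A <- as.matrix(structure[res, c("x", "y", "z")])
  B <- as.matrix(structure[lig, c("x", "y", "z")])
  .pairwise_min_dist(A, B)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate geometry: zero-length direction vector")
  v / n
}

#' Replace a residue's side chain with an idealized model of a new residue
#'
#' Re-implements single-conformation in-silico substitution: the side chain
#' is rebuilt as a straight chain of the new residue's heavy atoms extended
#' from CB along the CA-to-CB direction, one standard 1.53-Angstrom bond per
#' atom, collinear. Shrinking substitutions (to Ala/Gly/Ser...) simply
#' truncate. Backbone atoms (N, CA, C, O) are never moved. No rotamer
#' search is performed; clashes flagged on the extended conformation are a
#' deliberate, conservative surrogate for visual inspection.
#'
#' @param structure A `fgf_structure`.
#' @param position Residue number of the residue to mutate.
#' @param new_residue One-letter code of the replacement residue.
#' @param chain Optional chain id.
#' @return The mutated `fgf_structure` (atoms renumbered).
#' @export
mutate_residue <- function(structure, position, new_residue, chain = NULL) {
  new_residue <- toupper(new_residue)
  if (!new_residue %in% names(.AA3)) stop("unknown residue: ", new_residue)
  new3 <- .AA3[[new_residue]]
  res <- .residue_rows(structure, position, chain)
  rs <- structure[res, ]
  get_atom <- function(nm) {
    i <- which(rs$atom == nm)
    if (!length(i)) return(NULL)
    as.numeric(rs[i[1L], c("x", "y", "z")])
  }
  ca <- get_atom("CA"); n <- get_atom("N"); cc <- get_atom("C")
  if (is.null(ca) || is.null(n)) stop("residue ", position,
                                      " lacks backbone anchor atoms (N, CA)")
  cb <- get_atom("CB")
  keep_names <- if (new_residue == "G") .BACKBONE else c(.BACKBONE, "CB")
  body <- structure[setdiff(seq_len(nrow(structure)), res), ]
  kept <- rs[rs$atom %in% keep_names, ]
  new_atoms <- NULL
  if (new_residue != "G") {
    if (is.null(cb)) {
      if (is.null(cc)) stop("Gly residue ", position,
                            " lacks C anchor needed to build CB")
      # pseudo-CB along the tetrahedral bisector opposite N and C
      u_cb <- .unit(-(.unit(n - ca) + .unit(cc - ca)))
      cb <- ca + .CC_BOND * u_cb
      cb_row <- rs[1L, ]
      cb_row$atom <- "CB"; cb_row$element <- "C"
      cb_row$x <- cb[1]; cb_row$y <- cb[2]; cb_row$z <- cb[3]
      kept <- rbind(kept, cb_row)
    }
    u <- .unit(cb - ca)
    beyond <- .SIDECHAIN_BEYOND_CB[[new3]]
    if (length(beyond)) {
      coords <- t(vapply(seq_along(beyond),
                         function(j) cb + j * .CC_BOND * u, numeric(3)))
      new_atoms <- data.frame(
        eleno = 0L, atom = beyond, resname = new3,
        chain = kept$chain[1L], resno = position,
        x = coords[, 1], y = coords[, 2], z = coords[, 3],
        element = .element_of(beyond), is_ligand = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  kept$resname <- new3
  out <- rbind(body, kept[, names(body)],
               if (!is.null(new_atoms)) new_atoms[, names(body)])
  ord <- order(out$is_ligand, out$chain, out$resno,
               match(out$atom, c(.BACKBONE, "CB",
                                 unique(unlist(.SIDECHAIN_BEYOND_CB)))))
  out <- out[ord, ]
  out$eleno <- seq_len(nrow(out))
  .new_structure(out)
}

#' Detect steric clashes around one residue's side chain
#'
#' TRUE when any heavy atom of the residue's side chain (atoms other than
#' N, CA, C, O) lies closer than `clash_cutoff` to a heavy atom of a
#' non-adjacent residue or of the ligand. Atoms of the residue itself are
#' excluded, as are backbone atoms of the sequence neighbors (i +/- 1, same
#' chain); neighbor side chains do count.
#'
#' @param structure A `fgf_structure`.
#' @param position Residue number.
#' @param clash_cutoff Heavy-atom center distance threshold, Angstrom
#'   (default 2.4).
#' @param chain Optional chain id.
#' @return List with `clash` (logical) and `pairs` (data.frame of offending
#'   atom pairs with their distances).
#' @export
detect_clashes <- function(structure, position, clash_cutoff = 2.4,
                           chain = NULL) {
  res <- .residue_rows(structure, position, chain)
  res_chain <- structure$chain[res[1L]]
  side <- res[!structure$atom[res] %in% .BACKBONE]
  empty <- data.frame(atom = character(0), other_atom = character(0),
                      other_chain = character(0), other_resno = integer(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (!length(side)) return(list(clash = FALSE, pairs = empty))
  other <- setdiff(seq_len(nrow(structure)), res)
  neighbor_bb <- structure$chain[other] == res_chain &
    !structure$is_ligand[other] &
    abs(structure$resno[other] - position) == 1L &
    structure$atom[other] %in% .BACKBONE
  other <- other[!neighbor_bb]
  if (!length(other)) return(list(clash = FALSE, pairs = empty))
  A <- as.matrix(structure[side, c("x", "y", "z")])
  B <- as.matrix(structure[other, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  hit <- which(d2 < clash_cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(list(clash = FALSE, pairs = empty))
  pairs <- data.frame(
    atom = structure$atom[side[hit[, 1]]],
    other_atom = structure$atom[other[hit[, 2]]],
    other_chain = structure$chain[other[hit[, 2]]],
    other_resno = structure$resno[other[hit[, 2]]],
    distance = sqrt(pmax(0, d2[hit])),
    stringsAsFactors = FALSE)
  list(clash = TRUE, pairs = pairs[order(pairs$distance), ])
}
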