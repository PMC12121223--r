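#' Parse a point-mutation string
#'
#' @param x Character vector like `"S116R"` (wild-type residue, position,
#'   new residue). Whitespace is tolerated (`"S17 K"` reads as S17K).
#' @param scheme Numbering scheme the positions refer to.
#' @param tag Optional label (e.g. the mutation letter A-D, or
#'   "stability"/"fgfr").
#' @return data.frame with columns `wt`, `position`, `new`, `scheme`, `tag`.
#' @export
parse_mutation <- function(x, scheme = "gimenez_gallego", tag = NA_character_) {
  x <- gsub("[[:space:]]+", "", x)
  m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed mutation spec: ", paste(x[bad], collapse = ", "))
  wt <- toupper(vapply(m, `[`, character(1), 2L))
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  new <- toupper(vapply(m, `[`, character(1), 4L))
  if (any(wt == new)) stop("wild-type and new residue identical in: ",
                           paste(x[wt == new], collapse = ", "))
  data.frame(wt = wt, position = pos, new = new,
             scheme = rep_len(numbering_scheme(scheme)$name, length(x)),
             tag = rep_len(tag, length(x)), stringsAsFactors = FALSE)
}

.split_mutations <- function(s, tag = NA_character_) {
  if (!nzchar(s)) {
    return(parse_mutation(character(0))[0, ])
  }
  parse_mutation(strsplit(s, ",")[[1]], tag = tag)
}

#' Define a named variant as three mutation sets
#'
#' @param name Variant name.
#' @param hs,fgfr,stability Character vectors of mutation strings (GG
#'   numbering): heparan-sulfate affinity set, FGFR-disrupting set,
#'   stabilizing set. The three sets must be disjoint by position.
#' @return A `variant_definition` (list with the parsed sets).
#' @export
variant_definition <- function(name, hs = character(0),
                               fgfr = character(0),
                               stability = character(0)) {
  sets <- list(
    hs = if (length(hs)) parse_mutation(hs, tag = "hs") else parse_mutation(character(0)),
    fgfr = if (length(fgfr)) parse_mutation(fgfr, tag = "fgfr") else parse_mutation(character(0)),
    stability = if (length(stability)) parse_mutation(stability, tag = "stability") else parse_mutation(character(0))
  )
  pos <- unlist(lapply(sets, `[[`, "position"))
  if (anyDuplicated(pos)) stop("mutation sets of variant ", name,
                               " overlap by position")
  structure(c(list(name = name), sets), class = "variant_definition")
}

#' All mutations of a variant as one data.frame
#' @param variant A `variant_definition`.
#' @return data.frame of parsed mutations (hs + fgfr + stability).
#' @export
variant_mutations <- function(variant) {
  stopifnot(inherits(variant, "variant_definition"))
  rbind(variant$hs, variant$fgfr, variant$stability)
}

#' Apply point mutations to a protein sequence
#'
#' Every mutation's wild-type residue is checked against the sequence
#' (after numbering conversion) before any edit is made, so a numbering
#' offset bug fails loudly instead of silently mutating the wrong residue.
#' Length is preserved and exactly `nrow(mutations)` positions change.
#'
#' @param sequence Protein sequence (character scalar).
#' @param mutations A `variant_definition`, or a data.frame as returned by
#'   [parse_mutation()].
#' @param seq_scheme Numbering scheme of `sequence` (position 1 of the
#'   string is the first covered position of the scheme). Default
#'   "construct" (Met-Ala-FGF1(21-154), string index = construct position).
#' @return Mutated sequence (character scalar).
#' @export
apply_mutations <- function(sequence, mutations, seq_scheme = "construct") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (inherits(mutations, "variant_definition"))
    mutations <- variant_mutations(mutations)
  if (nrow(mutations) == 0L) return(sequence)
  seq_scheme <- numbering_scheme(seq_scheme)
  chars <- strsplit(sequence, "")[[1]]
  # string index i corresponds to scheme position i (schemes here start at 1
  # for full_length/GG; the construct string is indexed by construct position)
  idx <- integer(nrow(mutations))
  for (k in seq_len(nrow(mutations))) {
    idx[k] <- convert_numbering(mutations$position[k],
                                from = mutations$scheme[k], to = seq_scheme)
  }
  if (any(idx < 1L | idx > length(chars)))
    stop("mutation position outside the supplied sequence")
  found <- chars[idx]
  bad <- found != mutations$wt
  if (any(bad)) {
    k <- which(bad)[1L]
    stop("wild-type mismatch for ", mutations$wt[k], mutations$position[k],
         mutations$new[k], ": found '", found[k], "' at ", seq_scheme$name,
         " position ", idx[k])
  }
  chars[idx] <- mutations$new
  paste(chars, collapse = "")
}

#' Build the 13-variant biosensor panel
#'
#' Constructs the full combinatorial panel: the FGFR-uncoupled, stabilized
#' base molecule (FGF1_HS, no affinity mutation) plus the 12 combinations of
#' the four heparan-sulfate affinity mutations A = N114R, B = S116R,
#' C = S17K, D = L72R. Every variant carries the shared FGFR-disrupting and
#' stabilizing sets. Wild-type residues of all mutations are validated
#' against `base` before any sequence is emitted.
#'
#' @param base Base protein sequence, default the Met-Ala-FGF1(21-154)
#'   construct.
#' @param seq_scheme Numbering scheme of `base` (default "construct").
#' @return A named list of `variant_definition` objects (class
#'   `variant_panel`), each with a `$sequence` element holding the mutated
#'   sequence.
#' @export
build_variant_panel <- function(base = fgf1_construct_sequence(),
                                seq_scheme = "construct") {
  tab <- fgf1_variant_table()
  panel <- vector("list", nrow(tab))
  names(panel) <- tab$variant
  for (i in seq_len(nrow(tab))) {
    hs <- if (nzchar(tab$hs_mutations[i]))
      strsplit(tab$hs_mutations[i], ",")[[1]] else character(0)
    vd <- variant_definition(
      name = tab$variant[i], hs = hs,
      fgfr = strsplit(tab$fgfr_mutations[i], ",")[[1]],
      stability = strsplit(tab$stability_mutations[i], ",")[[1]]
    )
    vd$sequence <- apply_mutations(base, vd, seq_scheme = seq_scheme)
    panel[[i]] <- vd
  }
  structure(panel, class = "variant_panel", base = base)
}

#' Write a variant panel as FASTA and a mutation manifest CSV
#'
#' @param panel A `variant_panel` from [build_variant_panel()].
#' @param fasta_path,manifest_path Output paths (NULL to skip either).
#' @return Invisibly, the manifest data.frame
#'   (`variant,mutation,tag,scheme`).
#' @export
write_variant_panel <- function(panel, fasta_path = NULL,
                                manifest_path = NULL) {
  stopifnot(inherits(panel, "variant_panel"))
  seqs <- vapply(panel, `[[`, character(1), "sequence")
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta_path)
  }
  manifest <- do.call(rbind, lapply(panel, function(v) {
    mm <- variant_mutations(v)
    if (nrow(mm) == 0L) return(NULL)
    data.frame(variant = v$name,
               mutation = paste0(mm$wt, mm$position, mm$new),
               tag = mm$tag, scheme = mm$scheme, stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  if (!is.null(manifest_path)) {
    utils::write.csv(manifest, manifest_path, row.names = FALSE)
  }
  invisible(manifest)
}

#' Hamming distance between two equal-length sequences
#' @param a,b Character scalars of equal nchar.
#' @return Integer count of differing positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
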