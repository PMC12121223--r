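#' Amino-acid class partition used by the conservation rules
#'
#' Standard four-class partition: positively charged \{K,R,H\}, negatively
#' charged \{D,E\}, polar \{S,T,N,Q,C,Y,W\}, nonpolar \{A,V,L,I,M,F,P,G\}.
#' The partition is an argument of [classify_columns()] so alternative
#' groupings can be supplied.
#'
#' @return Named list of character vectors.
#' @export
aa_classes <- function() {
  list(
    positive = c("K", "R", "H"),
    negative = c("D", "E"),
    polar    = c("S", "T", "N", "Q", "C", "Y", "W"),
    nonpolar = c("A", "V", "L", "I", "M", "F", "P", "G")
  )
}

.check_alignment <- function(alignment) {
  if (!is.character(alignment) || length(alignment) == 0L)
    stop("alignment must be a non-empty named character vector")
  if (is.null(names(alignment)) || anyDuplicated(names(alignment)))
    stop("alignment rows must have unique ids")
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("all aligned sequences must have equal length")
  invisible(w)
}

.alignment_matrix <- function(alignment) {
  .check_alignment(alignment)
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Read / write an aligned FASTA file
#'
#' Thin wrappers over Biostrings; an alignment is represented as a named
#' character vector of equal-length gapped sequences.
#'
#' @param path File path.
#' @param alignment Named character vector of gapped sequences.
#' @return `read_alignment` returns the named character vector.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  aln <- toupper(as.character(x))
  names(aln) <- sub("\\s.*$", "", names(x))
  .check_alignment(aln)
  aln
}

#' @rdname read_alignment
#' @export
write_alignment <- function(alignment, path) {
  .check_alignment(alignment)
  Biostrings::writeXStringSet(Biostrings::BStringSet(alignment), path)
  invisible(path)
}

#' Classify alignment columns by conservation
#'
#' A column is `identical_conserved` when some residue occurs at least
#' `min_count` times; `class_conserved` when no residue reaches that count
#' but at least `min_count` residues (not all identical) share one
#' amino-acid class; otherwise `unconserved`. Gaps never count toward any
#' tally. `basic_support` counts K/R among the non-target rows (all rows
#' when `target_id` is NULL).
#'
#' @param alignment Named character vector of gapped sequences.
#' @param target_id Optional row id excluded from the basic-support count.
#' @param min_count Occurrence threshold for conservation (default 3).
#' @param classes Amino-acid class partition, see [aa_classes()].
#' @return data.frame with columns `column`, `class`, `basic_support`,
#'   `target_residue` (NA when `target_id` is NULL).
#' @export
classify_columns <- function(alignment, target_id = NULL, min_count = 3L,
                             classes = aa_classes()) {
  m <- .alignment_matrix(alignment)
  if (!is.null(target_id) && !target_id %in% rownames(m))
    stop("unknown target_id: ", target_id)
  class_of <- character(0)
  for (nm in names(classes)) class_of[classes[[nm]]] <- nm
  basic <- c("K", "R")
  n_col <- ncol(m)
  cls <- character(n_col)
  support <- integer(n_col)
  target_res <- rep(NA_character_, n_col)
  non_target <- if (is.null(target_id)) rownames(m) else
    setdiff(rownames(m), target_id)
  for (j in seq_len(n_col)) {
    col <- m[, j]
    res <- col[col != "-" & col != "."]
    counts <- table(res)
    if (length(counts) && max(counts) >= min_count) {
      cls[j] <- "identical_conserved"
    } else if (length(res) >= min_count) {
      cl_counts <- table(class_of[res], useNA = "no")
      cls[j] <- if (length(cl_counts) && max(cl_counts) >= min_count)
        "class_conserved" else "unconserved"
    } else {
      cls[j] <- "unconserved"
    }
    nt <- col[non_target]
    support[j] <- sum(nt %in% basic)
    if (!is.null(target_id)) target_res[j] <- col[target_id]
  }
  data.frame(column = seq_len(n_col), class = cls, basic_support = support,
             target_residue = target_res, stringsAsFactors = FALSE)
}

#' Find alignment columns eligible for basic-residue substitution
#'
#' Design criterion on the sequence side: keep columns where the target row
#' holds a non-basic, non-gap residue while at least `min_support` of the
#' other rows carry Lys or Arg at that position. Basic means \{K, R\}
#' exactly; His does not count. A gapped target cell disqualifies the
#' column; gaps in other rows simply do not contribute support (the absolute
#' threshold is kept).
#'
#' @inheritParams classify_columns
#' @param min_support Minimum K/R count among non-target rows (default 3).
#' @return The [classify_columns()] data.frame restricted to eligible
#'   columns.
#' @export
find_candidate_columns <- function(alignment, target_id, min_support = 3L) {
  if (missing(target_id)) stop("target_id is required")
  if (min_support < 1L) stop("min_support must be >= 1")
  cc <- classify_columns(alignment, target_id = target_id)
  keep <- !is.na(cc$target_residue) &
    !cc$target_residue %in% c("-", ".", "K", "R") &
    cc$basic_support >= min_support
  cc[keep, , drop = FALSE]
}
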