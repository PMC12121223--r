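#' Structure- and alignment-guided candidate design
#'
#' Reproduces the three-criterion screen for basic-residue substitutions
#' that raise heparin/heparan-sulfate affinity:
#' \enumerate{
#'   \item alignment support: Lys or Arg present at the same position in at
#'     least `min_support` of the other rows while the target residue is
#'     itself non-basic ([find_candidate_columns()]);
#'   \item no steric clash: the residue rebuilt as Lys/Arg by
#'     [mutate_residue()] must pass [detect_clashes()];
#'   \item ligand vicinity: minimum heavy-atom distance to the bound ligand
#'     at most `vicinity_cutoff` ([min_distance_to_ligand()]).
#' }
#' Sites where both Arg and Lys pass keep Arg (deterministic tie-break).
#' Candidates are ranked by ligand distance (ascending), then alignment
#' support (descending).
#'
#' @param alignment Named character vector of gapped sequences.
#' @param target_id Row id of the design target; its ungapped sequence is
#'   assumed to start at position 1 of `target_scheme`.
#' @param structure A `fgf_structure` with at least one ligand atom.
#' @param target_scheme Numbering scheme of the ungapped target sequence
#'   (default "gimenez_gallego").
#' @param structure_scheme Numbering scheme of the structure's residue
#'   numbers (default equal to `target_scheme`, i.e. no conversion).
#' @param vicinity_cutoff Maximum ligand distance, Angstrom (default 8).
#' @param clash_cutoff Clash distance threshold, Angstrom (default 2.4).
#' @param min_support Minimum K/R alignment support (default 3).
#' @return data.frame of retained candidates:
#'   `position,scheme,wt,proposed,support,min_dist_A,clash,rank`.
#' @export
design_candidates <- function(alignment, target_id, structure,
                              target_scheme = "gimenez_gallego",
                              structure_scheme = target_scheme,
                              vicinity_cutoff = 8.0, clash_cutoff = 2.4,
                              min_support = 3L) {
  cols <- find_candidate_columns(alignment, target_id, min_support)
  target <- alignment[[target_id]]
  chars <- strsplit(toupper(target), "")[[1]]
  is_res <- !chars %in% c("-", ".")
  ungapped_index <- cumsum(is_res)
  target_scheme <- numbering_scheme(target_scheme)
  structure_scheme <- numbering_scheme(structure_scheme)
  out <- list()
  for (r in seq_len(nrow(cols))) {
    j <- cols$column[r]
    pos_target <- ungapped_index[j]  # target scheme, sequence starts at 1
    pos_struct <- if (identical(target_scheme$name, structure_scheme$name))
      pos_target else
        tryCatch(convert_numbering(pos_target, target_scheme,
                                   structure_scheme),
                 error = function(e) NA_integer_)
    if (is.na(pos_struct)) {
      message("column ", j, ": position ", pos_target,
              " unmappable to the structure numbering; skipped")
      next
    }
    d <- tryCatch(min_distance_to_ligand(structure, pos_struct),
                  error = function(e) NA_real_)
    if (is.na(d)) {
      message("column ", j, ": residue ", pos_struct,
              " absent from the structure; skipped")
      next
    }
    if (d > vicinity_cutoff) next
    chosen <- NA_character_
    for (proposed in c("R", "K")) {  # Arg preferred when both pass
      mut <- mutate_residue(structure, pos_struct, proposed)
      if (!detect_clashes(mut, pos_struct, clash_cutoff)$clash) {
        chosen <- proposed
        break
      }
    }
    if (is.na(chosen)) next
    out[[length(out) + 1L]] <- data.frame(
      position = pos_target, scheme = target_scheme$name,
      wt = cols$target_residue[r], proposed = chosen,
      support = cols$basic_support[r], min_dist_A = d,
      clash = FALSE, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(position = integer(0), scheme = character(0),
                      wt = character(0), proposed = character(0),
                      support = integer(0), min_dist_A = numeric(0),
                      clash = logical(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # distances rounded to 1e-6 A for ranking so physically meaningless
  # floating-point differences cannot reorder ties
  ord <- order(round(res$min_dist_A, 6), -res$support, res$position)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Write a candidate report CSV
#' @param candidates data.frame from [design_candidates()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidate_csv <- function(candidates, path) {
  utils::write.csv(candidates, path, row.names = FALSE)
  invisible(path)
}
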