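#' Residue numbering schemes
#'
#' Mutation positions in the FGF1 literature are quoted in several numbering
#' systems. A scheme is defined by its offset to full-length (UniProt)
#' coordinates and the range of positions it covers:
#' \describe{
#'   \item{full_length}{UniProt P05230 positions 1-155 (offset 0).}
#'   \item{gimenez_gallego}{1-140 numbering of the mature 140-residue form;
#'     GG position g = full-length g + 15.}
#'   \item{construct}{Met-Ala-FGF1(21-154), 136 residues; positions 1-2 are
#'     the Met-Ala leader and carry no GG/full-length number; construct
#'     position p >= 3 = full-length p + 18.}
#' }
#' Conversion is a strict bijection on the covered overlap; positions that do
#' not map (e.g. the Met-Ala leader in GG coordinates) raise an error rather
#' than silently shifting.
#'
#' @param scheme Scheme name (one of the above) or a `residue_numbering`
#'   object.
#' @return A `residue_numbering` object (name, offset to full-length
#'   coordinates, covered range).
#' @examples
#' convert_numbering(17, "gimenez_gallego", "construct")  # 14
#' @export
numbering_scheme <- function(scheme) {
  if (inherits(scheme, "residue_numbering")) return(scheme)
  stopifnot(is.character(scheme), length(scheme) == 1L)
  known <- list(
    full_length     = list(offset = 0L,  range = c(1L, 155L)),
    gimenez_gallego = list(offset = 15L, range = c(1L, 140L)),
    construct       = list(offset = 18L, range = c(3L, 136L))
  )
  if (!scheme %in% names(known)) {
    stop("unknown numbering scheme: ", scheme,
         " (expected one of ", paste(names(known), collapse = ", "), ")")
  }
  structure(c(list(name = scheme), known[[scheme]]),
            class = "residue_numbering")
}

#' Convert a residue position between numbering schemes
#'
#' @param position Integer vector of positions valid in `from`.
#' @param from,to Scheme names or `residue_numbering` objects.
#' @return Integer vector of positions in `to`.
#' @export
convert_numbering <- function(position, from, to) {
  from <- numbering_scheme(from)
  to <- numbering_scheme(to)
  position <- as.integer(position)
  if (any(is.na(position))) stop("position must be integer")
  bad <- position < from$range[1L] | position > from$range[2L]
  if (any(bad)) {
    stop("position ", paste(position[bad], collapse = ","),
         " outside the covered range of scheme '", from$name, "'")
  }
  full <- position + from$offset
  out <- full - to$offset
  unmapped <- out < to$range[1L] | out > to$range[2L]
  if (any(unmapped)) {
    stop("position ", paste(position[unmapped], collapse = ","),
         " in scheme '", from$name, "' has no equivalent in scheme '",
         to$name, "' (unmapped)")
  }
  out
}
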