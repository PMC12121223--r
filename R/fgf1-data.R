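#' Reference sequences and published parameter tables for the FGF1 biosensor panel
#'
#' Human FGF1 (UniProt P05230, 155 aa) is the design target. All user-facing
#' mutation positions use the Gimenez-Gallego (GG) 1-140 numbering of the
#' 140-residue mature form (full-length residues 16-155); the expression
#' construct is Met-Ala-FGF1(21-154).
#'
#' @name fgf1_reference
NULL

# UniProt P05230, human FGF1, 155 residues.
.FGF1_FULL <- paste0(
  "MAEGEITTFTALTEKFNLPPGNYKKPKLLYCSNGGHFLRILPDGTVDGTR",
  "DRSDQHIQLQLSAESVGEVYIKSTETGQYLAMDTDGLLYGSQTPNEECLF",
  "LERLEENHYNTYISKKHAEKNWFVGLKKNGSCKRGPRTHYGQKAILFLPL",
  "PVSSD"
)

#' Full-length human FGF1 sequence
#' @return Character scalar, the 155-residue FGF1 sequence (UniProt P05230).
#' @export
fgf1_full_sequence <- function() .FGF1_FULL

#' Gimenez-Gallego numbered FGF1 sequence (positions 1-140)
#'
#' The 140-residue mature form: full-length residues 16-155. GG position g
#' corresponds to full-length position g + 15; all panel mutation
#' positions (e.g. S17K, L72R, N114R, S116R) index this sequence.
#' @return Character scalar of length 140.
#' @export
fgf1_gg_sequence <- function() substr(.FGF1_FULL, 16L, 155L)

#' Expression-construct FGF1 sequence: Met-Ala-FGF1(21-154)
#'
#' Met-Ala leader followed by full-length residues 21-154 (136 residues
#' total). Construct position p >= 3 corresponds to full-length p + 18 and
#' GG position p + 3.
#' @return Character scalar of length 136.
#' @export
fgf1_construct_sequence <- function() {
  paste0("MA", substr(.FGF1_FULL, 21L, 154L))
}

# Shared mutation sets (GG numbering) carried by every panel variant.
.FGFR_MUTATIONS      <- c("Y94A", "N95A")
.STABILITY_MUTATIONS <- c("C16S", "Q40P", "S47I", "C83S", "H93G", "C117S")

# Heparan-sulfate affinity mutations, lettered as in the study.
.HS_MUTATIONS <- c(A = "N114R", B = "S116R", C = "S17K", D = "L72R")

#' Published variant panel definition
#'
#' The 13 variants: the FGFR-uncoupled, stabilized base molecule (FGF1_HS)
#' plus 12 combinations of the four heparan-sulfate affinity mutations
#' A = N114R, B = S116R, C = S17K, D = L72R. Every variant carries the
#' FGFR-disrupting set \{Y94A, N95A\} and the stabilizing set
#' \{C16S, Q40P, S47I, C83S, H93G, C117S\}.
#'
#' @return data.frame with columns `variant`, `hs_mutations`
#'   (comma-separated, empty for the base), `fgfr_mutations`,
#'   `stability_mutations`.
#' @export
fgf1_variant_table <- function() {
  combos <- c("", "A", "B", "C", "D", "AB", "BC", "BD", "CD",
              "ABC", "ABD", "BCD", "ABCD")
  hs <- vapply(combos, function(cc) {
    if (!nzchar(cc)) return("")
    paste(.HS_MUTATIONS[strsplit(cc, "")[[1]]], collapse = ",")
  }, character(1))
  data.frame(
    variant = paste0("FGF1_HS", ifelse(nzchar(combos), "_", ""), combos),
    hs_mutations = unname(hs),
    fgfr_mutations = paste(.FGFR_MUTATIONS, collapse = ","),
    stability_mutations = paste(.STABILITY_MUTATIONS, collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Published melting temperatures of the panel (CD and fluorescence)
#'
#' Midpoint temperatures of two-state thermal denaturation followed by
#' circular dichroism at 228 nm and by Trp107 fluorescence at 353 nm, with
#' the shift relative to the base molecule (`dT_*`, in degrees C).
#'
#' @return data.frame with columns `variant`, `tm_cd`, `se_cd`, `dT_cd`,
#'   `tm_fl`, `se_fl`, `dT_fl`.
#' @export
fgf1_stability_table <- function() {
  data.frame(
    variant = c("FGF1_HS", "FGF1_HS_B", "FGF1_HS_C", "FGF1_HS_D",
                "FGF1_HS_BC", "FGF1_HS_BD", "FGF1_HS_CD", "FGF1_HS_BCD"),
    tm_cd = c(60.82, 61.35, 61.10, 65.84, 61.95, 65.92, 66.21, 66.15),
    se_cd = c(1.09, 0.07, 0.09, 0.09, 0.14, 0.03, 0.03, 0.03),
    dT_cd = c(0.00, 0.53, 0.28, 5.02, 1.13, 5.10, 5.39, 5.33),
    tm_fl = c(60.69, 62.92, 61.70, 64.64, 64.53, 64.44, 64.81, 66.32),
    se_fl = c(0.02, 0.04, 0.02, 0.02, 0.02, 0.06, 0.02, 0.02),
    dT_fl = c(0.00, 2.23, 1.00, 3.95, 3.83, 3.75, 4.12, 5.63),
    stringsAsFactors = FALSE
  )
}

#' Published heparin-column elution and glypican-4 binding kinetics
#'
#' Elution-peak conductivity (mS/cm) with the corresponding NaCl molarity on
#' a linear 0.5-2 M gradient, and biolayer-interferometry kinetic constants
#' (kon in 1/(uM s), koff in 1/s, KD = koff/kon in uM) for binding to
#' sensor-immobilized glypican-4.
#'
#' @return data.frame with columns `variant`, `conductivity_mS_cm`,
#'   `nacl_M`, `kon`, `kon_se`, `koff`, `koff_se`, `kd`, `kd_se`.
#' @export
fgf1_affinity_table <- function() {
  data.frame(
    variant = c("FGF1_HS", "FGF1_HS_B", "FGF1_HS_C", "FGF1_HS_D",
                "FGF1_HS_BC", "FGF1_HS_BD", "FGF1_HS_CD", "FGF1_HS_BCD"),
    conductivity_mS_cm = c(120.19, 125.86, 126.34, 125.89,
                           129.27, 131.43, 131.06, 134.27),
    nacl_M = c(1.37, 1.46, 1.47, 1.46, 1.52, 1.55, 1.55, 1.60),
    kon = c(0.19, 0.24, 0.27, 0.33, 6.83, 0.71, 0.29, 0.42),
    kon_se = c(0.04, 0.01, 0.01, 0.02, 1.65, 0.02, 0.01, 0.01),
    koff = c(1.43, 0.64, 0.61, 0.34, 0.52, 0.30, 0.24, 0.15),
    koff_se = c(0.19, 0.03, 0.02, 0.02, 0.12, 0.01, 0.01, 0.00),
    kd = c(7.37, 2.64, 2.27, 1.01, 0.08, 0.42, 0.81, 0.35),
    kd_se = c(1.71, 0.21, 0.13, 0.10, 0.03, 0.02, 0.03, 0.01),
    stringsAsFactors = FALSE
  )
}
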