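#!/usr/bin/env Rscript
# Build the 13-variant biosensor panel from the Met-Ala-FGF1(21-154)
# construct: the FGFR-uncoupled stabilized base molecule plus all
# combinations of the four heparin-affinity mutations (A=N114R, B=S116R,
# C=S17K, D=L72R). Writes the panel FASTA and the mutation manifest.

suppressPackageStartupMessages(library(fgfhs))
dir.create("results", showWarnings = FALSE)

panel <- build_variant_panel()
manifest <- write_variant_panel(panel,
                                fasta_path = "results/variant_panel.fasta",
                                manifest_path = "results/mutation_manifest.csv")

cat("Variant panel:", length(panel), "variants,",
    nchar(panel[[1]]$sequence), "residues each\n")
hs <- panel[["FGF1_HS"]]$sequence
for (v in names(panel)) {
  cat(sprintf("  %-14s %d mutations vs construct, %d vs FGF1_HS\n", v,
              nrow(variant_mutations(panel[[v]])),
              hamming_distance(hs, panel[[v]]$sequence)))
}
cat("FGF1_HS_BCD differs from FGF1_HS at Gimenez-Gallego positions ",
    paste(sort(vapply(
      which(strsplit(hs, "")[[1]] !=
              strsplit(panel[["FGF1_HS_BCD"]]$sequence, "")[[1]]),
      convert_numbering, integer(1),
      from = "construct", to = "gimenez_gallego")), collapse = ", "),
    "\n", sep = "")
cat("wrote results/variant_panel.fasta and results/mutation_manifest.csv\n")
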