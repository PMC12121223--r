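#!/usr/bin/env Rscript
# BLI kinetics of the variant panel against glypican-4: simulate
# three-concentration sensorgrams (0.2/0.4/0.8 uM, 450 s association +
# 450 s dissociation, 1% noise) at each variant's published rate
# constants, fit globally, and tabulate kon/koff/KD plus the fold-change
# against the base molecule FGF1_HS.

suppressPackageStartupMessages(library(fgfhs))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

tab <- fgf1_affinity_table()
rows <- list()
for (i in seq_len(nrow(tab))) {
  v <- tab$variant[i]
  sg <- simulate_sensorgram(tab$kon[i], tab$koff[i], rmax = 2,
                            concentrations = c(0.2, 0.4, 0.8),
                            spec = synthetic_spec(seed = seed + i))
  fit <- global_fit(sg, n_sites = 1)
  rows[[v]] <- data.frame(
    variant = v, kon = fit$kon, kon_se = fit$kon_se,
    koff = fit$koff, koff_se = fit$koff_se,
    kd = fit$kd_reported, kd_se = fit$kd_se)
}
out <- do.call(rbind, rows)
out$fold_vs_ref <- fold_change(out$kd[out$variant == "FGF1_HS"], out$kd)
rownames(out) <- NULL
write.csv(out, "results/kinetics_table.csv", row.names = FALSE)

cat("Global 1:1 fits of simulated sensorgrams (seed", seed, "):\n")
print(cbind(out[, c("variant", "kon", "koff", "kd", "fold_vs_ref")],
            kd_pub = tab$kd), digits = 3, row.names = FALSE)
cat(sprintf("FGF1_HS_BCD vs FGF1_HS fold-change: %.1f (published claim: > 20)\n",
            out$fold_vs_ref[out$variant == "FGF1_HS_BCD"]))
cat("wrote results/kinetics_table.csv\n")
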