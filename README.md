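# fgfhs

Reprogramming FGF1 into a heparan-sulfate biosensor, as a tested R
pipeline.

Fibroblast growth factor 1 (FGF1) naturally binds both heparan sulfate
(HS) on cell-surface proteoglycans and its signaling receptor (FGFR). To
turn it into an HS-specific molecular probe, the engineering program
implemented here combines, on one scaffold, FGFR-disrupting mutations
(Y94A, N95A), six stabilizing mutations (C16S, Q40P, S47I, C83S, H93G,
C117S), and basic-residue substitutions near the bound heparin chosen by a
three-criterion screen — A = N114R, B = S116R, C = S17K, D = L72R
(Gimenez-Gallego 1-140 numbering). The package implements:

* **Design screen** (`design_candidates()`): alignment columns where ≥ 3
  FGF paralogs carry Lys/Arg while the target residue is non-basic, the
  site rebuilt in silico as Arg/Lys without steric clash (idealized
  side-chain extension, 2.4 Å heavy-atom cutoff), and within 8 Å of the
  bound ligand.
* **Variant panel** (`build_variant_panel()`): the 13-variant combinatorial
  panel (FGF1_HS plus A-D combinations), with strict numbering conversion
  and wild-type validation of every edit.
* **Thermal denaturation** (`fit_two_state()`, `tm_from_derivative()`,
  `delta_tm()`): two-state van't Hoff model
  `K(T) = exp[(ΔH/R)(1/Tm − 1/T)]`, `fU = K/(1+K)`, linear baselines,
  ΔCp = 0; midpoint Tm with standard errors, plus a derivative-peak
  cross-check.
* **BLI kinetics** (`global_fit()`, `kd_from_rates()`, `fold_change()`):
  global multi-concentration fit of 1:1 or heterogeneous two-site
  sensorgram models; KD = koff/kon of the dominant site; affinity
  fold-changes.
* **Heparin-column elution** (`fit_calibration()`, `elution_peak()`):
  linear conductivity↔[NaCl] calibration on a 0.5-2 M gradient and
  parabolic peak extraction.
* **Synthetic data** (`simulate_sensorgram()`, `simulate_melting_curve()`,
  `simulate_elution()`, `make_toy_complex()`, `make_toy_alignment()`):
  seeded generators for every input the pipeline consumes, with known
  ground truth.

## Worked example

Simulate sensorgrams at the published FGF1_HS_BCD rate constants
(kon = 0.42 1/(µM·s), koff = 0.15 1/s) at 0.2/0.4/0.8 µM with 1% noise,
fit globally, and compare affinities:

```r
library(fgfhs)

tab <- fgf1_affinity_table()
bcd <- tab[tab$variant == "FGF1_HS_BCD", ]
sg  <- simulate_sensorgram(bcd$kon, bcd$koff, rmax = 2,
                           concentrations = c(0.2, 0.4, 0.8),
                           spec = synthetic_spec(seed = 42))
global_fit(sg, n_sites = 1)
#> Kinetic fit (1 site): kon = 0.422 1/(uM s), koff = 0.151 1/s, KD = 0.357 uM
#>   residual sd = 0.0139 (reported site 1 of 1)

fold_change(tab$kd[tab$variant == "FGF1_HS"], bcd$kd)
#> [1] 21.05714
```

The fitted constants recover the generating (published) values within
their printed uncertainties, and the KD ratio between the base molecule
(7.37 µM) and the triple mutant (0.35 µM) is 21-fold — the engineered
variant binds glypican-4 more than 20 times tighter. The design screen on
the bundled synthetic demonstration fixture recovers exactly the four
published candidate positions:

```r
demo <- fgf1_design_demo(seed = 1)
design_candidates(demo$alignment, demo$target_id, demo$structure)$position
#> [1] 114  17  72 116
```

The numbered scripts under `analysis/` run the full study: panel
construction, design screen, stability table, kinetics table, and elution
analytics, writing their tables under `results/`.

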