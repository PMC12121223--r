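---
title: "Methods: engineering and analyzing heparan sulfate-binding FGF1 variants"
author: "fgfhs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engineering and analyzing heparan sulfate-binding FGF1 variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfhs)
```

## The problem

Fibroblast growth factor 1 (FGF1) binds heparan sulfate (HS) chains of cell
surface proteoglycans through a cluster of basic residues, but it also binds
its signaling receptor (FGFR) with high affinity, which limits its use as an
HS-specific probe. The engineering strategy implemented here reprograms FGF1
into an HS biosensor by combining three mutation sets on one scaffold:

* an **FGFR-disrupting** pair, Y94A + N95A;
* a **stabilizing** set, C16S, Q40P, S47I, C83S, H93G, C117S, which raises
  the melting temperature of the scaffold by over 20 °C;
* **HS-affinity** substitutions that add basic residues near the bound
  heparin: A = N114R, B = S116R, C = S17K, D = L72R.

The base molecule carrying only the first two sets is called FGF1_HS; the
panel comprises FGF1_HS plus the 12 combinations of A-D (13 variants). All
positions use the Gimenez-Gallego (GG) 1-140 numbering of the mature
140-residue FGF1.

`fgfhs` implements the computational content of this program as a tested
pipeline: the design screen that proposes the A-D sites, the panel
construction, and the quantitative analyses used to characterize the
variants (two-state thermal denaturation, biolayer-interferometry kinetics,
heparin-column elution), together with a synthetic-data module that
generates every instrument input with known ground truth.

## Residue numbering

Three coordinate systems coexist in the FGF1 literature and in this
package:

| scheme            | covers  | relation to full-length (UniProt P05230) |
|-------------------|---------|------------------------------------------|
| `full_length`     | 1-155   | identity                                 |
| `gimenez_gallego` | 1-140   | GG *g* = full-length *g* + 15            |
| `construct`       | 3-136   | construct *p* = full-length *p* + 18     |

The expression construct is Met-Ala-FGF1(21-154): two leader residues
followed by full-length residues 21-154, so construct position *p* ≥ 3
corresponds to GG position *p* + 3, and GG positions 1-5 and 140 have no
construct equivalent. The offsets are not asserted by fiat: the test suite
re-derives them by exact string matching of the three sequences, and every
panel mutation (C16, S17, Q40, S47, L72, C83, H93, Y94, N95, N114,
S116, C117) is verified against its wild-type residue before any edit.
`convert_numbering()` is a strict bijection on the covered overlap;
unmapped positions (e.g. the Met-Ala leader) raise an error rather than
silently shifting — this guards against the classic off-by-constant
numbering bug in mutagenesis code.

```{r}
convert_numbering(17, "gimenez_gallego", "construct")
panel <- build_variant_panel()
length(panel)
hamming_distance(panel[["FGF1_HS"]]$sequence,
                 panel[["FGF1_HS_BCD"]]$sequence)
```

## The design screen

`design_candidates()` reproduces the three published selection criteria:

1. **Alignment support.** A position is eligible when the target row holds
   a non-basic, non-gap residue while at least `min_support = 3` other rows
   of the FGF paralog alignment carry Lys or Arg there. "Basic" is
   \{K, R\} exactly — His is excluded because the rule as stated names only
   Lys and Arg. The target's own residue never counts toward support, and a
   gapped target cell disqualifies the column; gaps in other rows reduce
   effective support but the absolute threshold is kept.
2. **No steric clash.** The site is rebuilt as Arg and as Lys with an
   idealized side chain — heavy atoms placed collinearly along the CA→CB
   direction at 1.53 Å per bond — and rejected when any side-chain atom
   comes within `clash_cutoff = 2.4` Å of a non-adjacent residue or the
   ligand (sequence neighbors' backbone excluded). No rotamer search is
   performed: the original screen was a single-conformation visual check in
   a modeling GUI, and a distance criterion on one extended conformation is
   the reproducible surrogate. It is deliberately conservative; flagged
   false positives can be relaxed via the cutoff.
3. **Ligand vicinity.** The minimum heavy-atom distance from the residue to
   the bound heparin must be at most `vicinity_cutoff = 8` Å. Eight
   ångströms spans a salt bridge plus side-chain reach, which matches the
   qualitative "in the vicinity of heparin" requirement; it is a tunable
   argument.

When both Arg and Lys pass at a site, Arg is kept (three of the four
published candidates are arginines); the tie-break is deterministic.
Candidates are ranked by ligand distance, then support — the published work
claims a candidate *set*, not an ordering, so the ranking is a convenience,
and distances are rounded to 10^-6 Å before ranking so floating-point noise
cannot reorder ties. Conservation classes for alignment display
(`classify_columns()`) use the standard four-class partition — positive
\{K,R,H\}, negative \{D,E\}, polar \{S,T,N,Q,C,Y,W\}, nonpolar
\{A,V,L,I,M,F,P,G\} — which is configurable, since the class memberships are
a convention rather than part of the rule.

The end-to-end demonstration (`fgf1_design_demo()`) is synthetic: the real
GG-numbered FGF1 sequence is embedded in a toy alignment with basic support
planted at columns 17, 72, 114 and 116 and in a toy ligand-bound complex
with those residues anchored 5 Å from a pseudo-ligand, plus two decoys (one
far from the ligand, one planted to clash). Recovering exactly
\{17, 72, 114, 116\} validates the screening logic on the real target
sequence — it does not re-derive the sites from crystallographic geometry,
which would require the deposited structures.

## Two-state thermal denaturation

Melts followed by circular dichroism (228 nm) or Trp107 fluorescence
(353 nm) are modeled as equilibrium two-state unfolding with linear
baselines:

$$K(T) = \exp\!\left[\frac{\Delta H_{vH}}{R}\left(\frac{1}{T_m} -
\frac{1}{T}\right)\right], \qquad f_U = \frac{K}{1+K},$$

$$S(T) = (1 - f_U)(a_N + b_N T) + f_U (a_D + b_D T),$$

with absolute temperatures inside $K(T)$ (conversion is exactly
$T_K = T_C + 273.15$) and ΔCp fixed at 0: a heat-capacity term is not
identifiable from a single melt, and only midpoints are compared. FGF1
unfolding is not strictly reversible; as in the source analysis, the
equilibrium model is applied at a fixed 1 °C/min scan rate and the fitted
midpoint is interpreted as an apparent Tm.

`fit_two_state()` fits all six parameters by Levenberg-Marquardt least
squares. Initialization is data-driven: Tm from the smoothed derivative
peak, baselines from straight-line fits of the outer 20% of points, and
ΔH from the derivative peak height via
$df_U/dT|_{T_m} = \Delta H / (4 R T_m^2)$. Standard errors come from the
fit covariance. Two estimators are reported on purpose — the full two-state
fit (the tabulated Tm) and the derivative-peak location
(`tm_from_derivative()`, a 5-point moving-average smoothed finite
difference with parabolic refinement, window configurable) — because the
original peak-fitting workflow is not described in enough detail to pick
one; on clean two-state data they agree to within the grid resolution.

Degenerate inputs are rejected rather than silently fitted: a monotone
(transition-free) signal has no interior derivative extremum, and a curve
truncated mid-transition fails a robust baseline check (the heavily
smoothed derivative must decay below 30% of its peak at both scan ends,
and at least 5 points are required on each side of the inflection). The
channel label uses 228 nm throughout; one figure legend in the source
prints 227 nm, a discrepancy we note and ignore.

## BLI kinetics

Sensorgrams are modeled as pseudo-first-order binding with one or two
independent site populations (the "heterogeneous ligand (1:1)" model used
by the instrument software is the two-site case):

$$R_{assoc}(t) = \sum_i \frac{R_{max,i}\,C}{C + K_{D,i}}
\left(1 - e^{-(k_{on,i} C + k_{off,i}) t}\right), \qquad
R_{dissoc}(t) = \sum_i R_i(t_{assoc})\, e^{-k_{off,i} t}.$$

Mass-transport limitation and analyte depletion are ignored, matching the
vendor model's assumptions. Concentrations are µM throughout (the published
rate unit is 1/(µM·s)); nM inputs are converted at the I/O boundary.

`global_fit()` fits all concentrations and both phases jointly: rates are
global, per-site Rmax is shared across concentrations. Initialization uses
a log-linear fit of the dissociation tail (koff) and the observed-rate
versus concentration regression (kon). Which site of a heterogeneous fit
the single published (kon, koff, KD) triple refers to is not stated; the
dominant-Rmax site is reported, with both sites retained in the output.
Reference-sensor subtraction is assumed done upstream;
`subtract_reference()` handles paired traces when both are available.
`binding_screen()` gives the qualitative bound/not-bound readout used for
receptor-binding controls.

## Heparin-column elution

On a linear 0.5-2 M NaCl gradient, conductivity is proportional to salt
molarity. `fit_calibration()` estimates the line by ordinary least squares
from (conductivity, molarity) pairs — the calibration is always
data-derived, never hard-coded, because the buffer's baseline conductivity
is not published. `elution_peak()` locates the A280 maximum, refines it by
three-point parabolic interpolation (the chromatography-software convention
for near-symmetric peaks; peak-maximum rather than centroid is assumed for
the published readings), and converts through the calibration. Ranking
variants by peak conductivity and by converted molarity are identical
orderings because the map is strictly monotone. Additivity of the
mutations' elution shifts is reported as a diagnostic by the analysis
script, not enforced.

## Synthetic data: what it emulates and what it does not

Every generator takes an explicit `synthetic_spec(seed, noise_sd, ...)`;
identical specs give bit-identical output and the global RNG state is
saved and restored around every draw. Defaults encode the study
conditions: sensorgrams at 200/400/800 nM with 450 s + 450 s phases
sampled at 2 Hz; melts on a 20-90 °C grid at 0.5 °C steps (the instruments
scanned at 1 °C/min; grid density is a free choice); elution on a 30 mL
0.5-2 M gradient. Noise is Gaussian, homoscedastic, defaulting to 1% of
the curve's dynamic range — instrument noise is not published, and 1% is
conservative for modern BLI/CD hardware. Two quantities the published
tables do not print are fixed once as realistic instrument-scale values
and never tuned: Rmax = 2 sensor units for simulated sensorgrams and
ΔH = 300 kJ/mol for simulated melts (a typical van't Hoff enthalpy for a
small β-trefoil protein).

The generators deliberately do **not** emulate: baseline drift or
reference-channel artifacts, mass-transport-limited association, unfolding
irreversibility or scan-rate dependence, real side-chain rotamers or
crystallographic geometry (the toy complex is a regular backbone with a
rigid 5-atom pseudo-ligand), or real instrument file dialects (only the
generic CSV schemas are supported, since the raw exports sit in an
access-protected deposit). Passing round-trip tests therefore demonstrates
correctness of the estimators under the stated model, not robustness to
every artifact of real traces.

## Numerical choices and problem sizes

* Nonlinear fits use `minpack.lm::nlsLM` with tight tolerances
  (ftol = ptol = 1e-14); noiseless round-trips recover generating
  parameters to ≤ 1e-6 relative error, which the suite asserts.
* Geometry screens are validated against brute-force all-pairs oracles on
  random structures (up to a few hundred atoms) and are invariant to
  rigid-body motion and atom order.
* Replicated-recovery tests use 25 melt replicates and 15 sensorgram
  replicates at 1% noise — enough to bound the bias below the published
  uncertainties while keeping the default test run fast.
* Sequence edits are order-independent within a variant and length-
  preserving; re-applying a mutation fails the wild-type check by design.

## Reproducing the analyses

The `analysis/` scripts are thin narrative drivers over the package:
`01_variant_panel.R` (panel FASTA + mutation manifest),
`02_design_screen.R` (candidate table on the synthetic demo),
`03_thermostability.R` (Tm table from simulated melts),
`04_bli_kinetics.R` (kon/koff/KD table and fold-changes from simulated
sensorgrams), `05_elution.R` (calibration, recovered elution peaks,
additivity diagnostic). `scripts/acceptance.R` recomputes the headline
numbers end to end and writes them as JSON.

## Known limitations

The design screen's clash test on an idealized extended side chain can
reject sites a rotamer search would accept. The two-state fit reports
apparent midpoints for a process that is not fully reversible. The
heterogeneous-ligand fit is only identifiable when the two site
populations differ enough in rates; with nearly equal sites it degenerates
to the 1:1 model (the nested-model test covers the well-separated case).
The synthetic demo validates pipeline logic, not crystallographic
reality.
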