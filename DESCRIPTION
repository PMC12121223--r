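Package: fgfhs
Title: Engineering and Biophysical Analysis of Heparan Sulfate-Binding FGF1 Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for reprogramming fibroblast growth factor 1 (FGF1)
    into a heparan-sulfate biosensor: alignment- and structure-guided design
    of basic-residue substitutions near the heparin-binding site, definition
    of the combinatorial variant panel, two-state van't Hoff analysis of
    thermal denaturation (CD and fluorescence melts), global fitting of
    biolayer-interferometry sensorgrams (1:1 and heterogeneous two-site
    models) with dissociation-constant and fold-change reporting, and
    heparin-column elution analytics with linear conductivity-to-molarity
    gradient calibration. A synthetic-data module generates every input the
    pipeline consumes (toy ligand-bound structures, toy alignments,
    sensorgrams, melting curves, elution profiles) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
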