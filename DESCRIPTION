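Package: TailOrder
Title: Disorder-to-Order Analysis of G Protein Gamma-Subunit N-Terminal Tails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying intrinsically disordered N-terminal tails of
    heterotrimeric G protein gamma subunits and their engineered transition to
    alpha-helical order. Implements propensity-based secondary-structure and
    disorder profiling of short peptides, greedy design of minimal
    helix-stabilizing mutation paths with isometric controls, decomposition of
    far-UV circular dichroism spectra into helix/sheet/coil fractions by
    simplex-constrained least squares, marginal ancestral sequence
    reconstruction with per-node N-terminal disorder-length annotation, and
    inscribed-circle morphometry of yeast mating projections (shmoos) from
    binary cell masks. A synthetic-data module generates every input with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
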