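---
title: "Disorder-to-order design and quantitation for Gγ N-terminal tails"
author: "TailOrder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disorder-to-order design and quantitation for Gγ N-terminal tails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TailOrder)
```

# Scope and scientific background

G protein γ subunits carry short intrinsically disordered N-terminal tails.
TailOrder supports a workflow built around the yeast subunit Ste18: quantify
disorder across a protein family and its reconstructed ancestors, design a
minimal ladder of point mutations that drives the tail from random coil to
α-helix, decompose circular dichroism (CD) spectra of the designed peptides
into secondary-structure fractions, and measure the yeast mating-projection
(shmoo) morphology that responds to the engineered tails. Every stage can be
exercised at desk scale on synthetic inputs with known ground truth; the
package never claims to reproduce the numerical output of the external
neural predictors (secondary-structure and disorder servers, CD
deconvolution services) that a wet-lab study would also consult — those
tools disagree among themselves at the margin, and only ordinal behavior is
promised here.

# Secondary structure and disorder metrics

## The helix/sheet predictor

`predictSS()` implements a classical Chou–Fasman-style procedure, chosen
because it is deterministic, fully reimplementable from shipped config data,
and reproduces the qualitative monotone helix ladder the design loop needs:

* **Nucleation.** A helix segment nucleates at any 6-residue window with at
  least 4 residues of Pα > 1.00 and window mean Pα > 1.03. Sheets nucleate
  analogously on 5-residue windows with at least 3 residues of Pβ > 1.00
  and the same mean margin (the classical sheet rule's mean threshold is
  stated inconsistently across texts; we mirror the helix margin and expose
  it as a parameter).
* **Extension.** Segments grow one residue at a time in both directions
  while the trailing 4-residue mean propensity stays ≥ 1.00; proline
  terminates N-ward helix extension.
* **Conflict.** Overlapping helix and sheet segments are resolved by the
  larger segment mean propensity, ties to helix. Everything else is coil.

All four propensity scales (Chou–Fasman Pα and Pβ, TOP-IDP disorder
propensity, Kyte–Doolittle hydropathy) live in `inst/extdata/` as
plain-text `residue=value` files and are never hard-coded; `readScale()`
accepts user replacements.

Peptides shorter than the nucleation window are therefore all-coil, poly-Gly
and poly-Pro can never nucleate (Pα 0.57), and `(AEAL)₄` saturates to
all-helix — the three limiting behaviors the test suite pins down.

## Disorder profiles

`disorderProfile()` averages the TOP-IDP value over a centered window
(default 5 residues, truncated — not padded — at the termini) and maps the
result to [0, 1] by min–max normalization against the scale's own extreme
values (W = −0.884, P = 0.987), so the bounds are fixed properties of the
configured scale rather than of the peptide. The disorder call threshold
defaults to 0.5 of that normalized range. `ntermDisorderLength()` then
reports the maximal prefix whose every residue clears the threshold —
matching the "length of N-terminal disorder" statistic used to annotate
family trees. These choices promise *ordinal* agreement with neural
predictors (longer designed prefixes score longer), not numerical identity.

## Relative hydrophobicity

No standard formula exists for a "relative hydrophobicity %" between two
peptides, and a plain ratio of Kyte–Doolittle means is ill-behaved because
the scale spans zero. We therefore shift the scale affinely so its minimum
(Arg, −4.5) is zero before taking means; the reference peptide maps to
exactly 100. A reference of pure arginine is the single degenerate case and
is rejected. This convention is a package decision, flagged as such.

# Greedy mutation-path design

`greedyHelixPath()` scores all `19·L` single substitutions each iteration
and fixes the strictly best one. Design decisions:

* **Insertions unlock only at substitution plateaus**, and at most one
  insertion is accepted per plateau event before the search returns to
  substitutions. This mirrors how an insertion is the move of last resort
  when substitutions alone cannot push helicity further.
* **Strict improvement, no epsilon.** Scores from the shipped predictor are
  rationals (`#H/L`), so exact comparison is well-defined and avoids hidden
  tolerance knobs; the search provably terminates because the score takes
  finitely many values on bounded-length sequences.
* **Tie-break:** lowest position, then alphabetically earliest target
  residue — purely for reproducibility; the enumeration order makes the
  first maximum the winner.
* **Scorer contract.** The scorer is called twice on the wildtype and must
  return identical values; a nondeterministic scorer is rejected up front.

The brute-force oracle in the tests materializes every variant at every step
and takes the argmax independently; greedy output must match it exactly on
peptides of length ≤ 8.

`isometricControl()` rebuilds the path's edit positions with control
residues: C1 minimizes the scorer per position over all 19 alternatives
(operationalizing "preserve disordered structure" as minimal predicted
helicity, since no other metric is specified), and C2 maximizes it within
the wildtype residue's physicochemical class (default partition:
hydrophobic AVILM, aromatic FWY, polar-uncharged STNQ, positive KRH,
negative DE, special GPC; shipped as config and overridable). A singleton
class leaves C2 undefined at that position and errors rather than guessing.

# CD spectral decomposition

Three canonical basis bands (helix, sheet, coil) are sums of Gaussian
components with all centers/widths/amplitudes in `inst/extdata/cd_bands.txt`
(units: 10³ deg·cm²·dmol⁻¹ mean residue ellipticity). The defaults encode
the textbook far-UV signatures — helix positive near 193 nm with the double
minimum at 208/222 nm, coil negative near 200 nm — and the `BasisSet`
validity enforces those signs, so a misconfigured basis fails fast. An
eight-component professional basis would be needed to resolve sheet
topologies; three states suffice to *rank* helix content across a peptide
ladder, which is the use case here.

`fitFractions()` minimizes `‖y − Xf‖²` over the probability simplex. With
three states the constrained optimum is found exactly by enumerating the
seven faces of the simplex (interior, three edges, three vertices) and
solving each equality-constrained subproblem in closed form via SVD
pseudo-inverse — no iterative solver, no tolerance tuning; a collinear basis
degrades to the minimum-norm solution with a warning. Spectra on mismatched
grids are linearly interpolated onto the basis grid; extrapolation is
refused. For measured spectra of unknown concentration, `fitScale = TRUE`
drops the sum constraint (non-negative least squares over the three
coefficients, again by exact active-set enumeration) and returns the
implied positive amplitude separately; the flag defaults to off because
synthetic tests state their world on the simplex.

`relativeHelixPercent()` requires an explicit reference decomposition
rather than assuming one, since which peptide anchors the comparison is a
reporting choice, not a property of the data.

# Marginal ancestral reconstruction

The reconstruction machinery — not any particular substitution model — is
the contract. `substitutionModel()` assembles a reversible 20-state CTMC
from symmetric exchangeabilities (WAG shipped as plain-text config; any
symmetric matrix accepted) and stationary frequencies, typically the
alignment-derived counts from `estimateFrequencies()` (use a positive
pseudocount so every frequency is strictly positive). Q is normalized to
one expected substitution per site per unit branch length, with a single
global rate factor (default 1.0) standing in for rate heterogeneity.
`transitionMatrix()` computes `P(t) = exp(Q·r·t)` from the cached
eigendecomposition of the symmetrized generator — stable, exactly
reversible, and fast enough to be called once per edge.

`marginalASR()` combines the upward Felsenstein pruning pass with downward
messages: `P(x_v | leaves) ∝ D_v(x)·L_v(x)`, where `L_v` is the partial
likelihood of the subtree below `v` and `D_v` the probability of the data
outside it. Numerical conventions:

* Gaps are missing data (all-ones partials), not a 21st state; a fully
  gapped column returns the stationary prior exactly.
* Partial likelihoods are *not* column-rescaled: at the tens-of-leaves desk
  scale this package targets, doubles never approach underflow, and an
  explicit guard stops the computation with a clear message if a much larger
  tree is attempted. Posterior normalization is per column at the end.
* MAP ties break alphabetically (within 1e-12) for determinism.
* Trees must arrive rooted with branch lengths; no rooting procedure is
  offered.

The tests hold this implementation to a 20-state closed-form enumeration at
two leaves (1e-12), to exhaustive 20³-state enumeration on a four-leaf tree,
and to phangorn's independent pruning implementation for the total
likelihood. (phangorn's own "marginal" ancestral states differ from the
exact marginal posterior by ~1e-3 on internal nodes, which is why it serves
as a likelihood oracle only.)

`annotateDisorderLengths()` ungaps each leaf's aligned sequence and each
internal node's MAP sequence before profiling, since the disorder window is
a property of the physical chain, not of alignment columns. How gaps inside
an N-terminal region should interact with length measurement is genuinely
underdetermined; ungapping first is the simplest defensible convention.

# Shmoo morphometry

"Largest inscribed circle" is operationalized through the exact Euclidean
distance transform (two-pass Felzenszwalb–Huttenlocher on squared
distances), with everything outside the image frame counting as background —
so a lone foreground pixel has radius 1 and a full-frame mask still finds
its center. Ties in the maximal distance go to the smallest (row, col).
Coordinates are R's native 1-based matrix indices.

The body is the inscribed circle of the whole mask; the remainder (pixels
farther than the body radius from the body center) is decomposed into
8-connected components and the *largest* hosts the shmoo circle — smaller
components are rasterization crumbs or secondary lobes and are logged, not
measured. Length runs along the ray through the two circle centers, from
the body-circle boundary to the last foreground point before exiting the
mask, marched at 0.25 px with bilinear interpolation thresholded at 0.5.
Width is measured perpendicular at the axis midpoint; a shmoo must exceed
one pixel of length to have a width, and a one-sided crossing reports
width 1 — both conventions adopted from the original measurement protocol.
`analyzeLabels()` applies a ≥ 5 px size filter in batch mode, replacing the
manual curation step of removing improperly segmented cells. Pathological
masks whose shmoo circle exceeds the body circle keep the EDT-maximal
circle as the body and carry a flag. Lengths are reported in pixels; users
with calibrated optics can multiply by their pixel size.

Mask I/O is plain-text integer matrices only: no PNG reader is available to
R in the supported environment, and text masks diff cleanly under version
control.

# The synthetic world

Generators state their world once and the tests measure against it; no
generator parameter was revisited after seeing a test outcome.

* **Shmoo masks** (`makeShmooMask()`): a disc of radius `R` plus a capsule
  of half-width `w/2` whose rounded cap ends exactly `L` pixels beyond the
  disc boundary; pixels are foreground iff their *center* lies inside the
  continuous shape, matching the sub-half-pixel accuracy the morphometry
  tests promise. Default geometry (body radius 20, lengths 10–30, widths
  5–11) spans the shapes a 60× yeast micrograph produces. `L = 0` collapses
  to a pure disc because the capsule then lies entirely inside the body.
* **CD spectra** (`simulateCDSpectrum()`): exact mixtures plus i.i.d.
  Gaussian noise scaled to the maximum absolute basis amplitude; 5% noise
  approximates a well-averaged far-UV measurement.
* **Evolution** (`evolveSequences()`): substitution-only simulation along
  the tree by direct sampling from `P(t)` — no indels, so alignment is the
  identity and recovery tests isolate the reconstruction machinery.
  `makeDisorderedFamily()` draws an 8-residue prefix (default) from strong
  disorder promoters {P, E, K, S, Q} and a 40-residue core from order
  promoters {W, F, I, L, M, V, Y}, the two pools sitting far on either side
  of the normalized 0.5 threshold so the designed boundary is sharp at low
  divergence (branch lengths 0.02–0.05).
* Every generator is a pure function of (parameters, seed): RNG state is
  saved and restored around each call, and ground truth travels in a
  machine-readable record beside each artifact.

What a green test does **not** establish: real micrographs have segmentation
errors and concave cells the capsule world lacks; real CD spectra carry
aromatic side-chain contributions and baseline drift; real protein families
evolve with indels and rate heterogeneity. The synthetic world validates
the algorithms' correctness, not their field accuracy.

# Statistics layer

`relativePercent()` (reference maps to exactly 100), `pearsonR()` with
explicit preconditions (n ≥ 3, non-constant), and `threewayCorrelation()`
for the helix/abundance/hydrophobicity association across peptide variants.
Pearson is the default because the designed ladders look linear on the
relative scales; a Spearman switch is provided to avoid over-claiming
linearity. The 3×3 matrix is a package convenience for exploring the
association — no hypothesis testing is attached to it, and ANOVA-style
group comparisons are deliberately out of scope.

# Known limitations

* The predictor reproduces Chou–Fasman-class accuracy, not neural-network
  accuracy; paths it designs are optimal only against its own scorer.
* Without column rescaling, `marginalASR()` is limited to roughly a hundred
  leaves before the underflow guard triggers.
* The three-band CD basis cannot separate parallel from antiparallel sheet
  or resolve polyproline-II coil; helix ranking is its validated use.
* The greedy search examines single edits only; it can miss multi-edit
  optima by construction, matching the iterative protocol it models.
* `shmooWidth()` measures at the axis midpoint only, so strongly tapered
  projections report their mid-shaft width, not an average.
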