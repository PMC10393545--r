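#' @import methods
NULL

#' The twenty canonical amino acids
#'
#' One-letter codes in the conventional order (alphabetical by three-letter
#' code) used for all substitution-model matrices in the package.
#'
#' @export
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Peptide: a short amino-acid sequence with an identifier
#'
#' Central unit of all sequence metrics. The sequence must be non-empty,
#' uppercase, and drawn from the 20 canonical amino acids (no gaps, no
#' ambiguity codes).
#'
#' @slot id single character label.
#' @slot sequence single character string over the 20-letter alphabet.
#'
#' @examples
#' Peptide("MTSVQ", id = "wt")
#' @export
setClass("Peptide", representation(id = "character", sequence = "character"))

setValidity("Peptide", function(object) {
  if (length(object@id) != 1L || is.na(object@id))
    return("'id' must be a single non-NA string")
  s <- object@sequence
  if (length(s) != 1L || is.na(s) || !nzchar(s))
    return("'sequence' must be a single non-empty string")
  bad <- setdiff(strsplit(s, "")[[1]], AMINO_ACIDS)
  if (length(bad))
    return(sprintf("invalid residue(s): %s (sequence must be uppercase over the 20 canonical amino acids)",
                   paste(unique(bad), collapse = ", ")))
  TRUE
})

#' @rdname Peptide-class
#' @param sequence amino-acid string.
#' @param id sequence label.
#' @export
Peptide <- function(sequence, id = "peptide") {
  new("Peptide", id = as.character(id), sequence = toupper(as.character(sequence)))
}

setMethod("show", "Peptide", function(object) {
  cat(sprintf("Peptide '%s' (%d aa)\n  %s\n",
              object@id, nchar(object@sequence), object@sequence))
})

#' PropensityScale: a per-residue numeric scale
#'
#' Maps each of the 20 canonical amino acids to a real number. Used for helix
#' (P-alpha) and sheet (P-beta) conformational propensities, disorder
#' propensity, and hydropathy; all scales ship as plain-text config files.
#'
#' @slot name scale label.
#' @slot values named numeric vector, exactly one finite entry per amino acid.
#' @export
setClass("PropensityScale",
         representation(name = "character", values = "numeric"))

setValidity("PropensityScale", function(object) {
  v <- object@values
  if (length(v) != 20L || !setequal(names(v), AMINO_ACIDS))
    return("'values' must have exactly one entry per canonical amino acid")
  if (any(!is.finite(v))) return("all scale values must be finite")
  TRUE
})

#' @rdname PropensityScale-class
#' @param values named numeric vector over the 20 amino acids.
#' @param name scale label.
#' @export
PropensityScale <- function(values, name = "scale") {
  new("PropensityScale", name = as.character(name),
      values = values[AMINO_ACIDS])
}

setMethod("show", "PropensityScale", function(object) {
  cat(sprintf("PropensityScale '%s' [%.3g, %.3g]\n", object@name,
              min(object@values), max(object@values)))
})

#' DisorderProfile: per-residue disorder scores for one peptide
#'
#' Scores lie in [0, 1] (1 = strongly disorder-promoting); the threshold
#' defines which residues count as disordered for prefix-length measurement.
#'
#' @slot scores numeric vector in [0, 1], one per residue.
#' @slot threshold single number in (0, 1).
#' @slot peptide the scored [Peptide-class].
#' @export
setClass("DisorderProfile",
         representation(scores = "numeric", threshold = "numeric",
                        peptide = "Peptide"))

setValidity("DisorderProfile", function(object) {
  if (length(object@scores) != nchar(object@peptide@sequence))
    return("one score per residue required")
  if (any(object@scores < -1e-12 | object@scores > 1 + 1e-12))
    return("scores must lie in [0, 1]")
  th <- object@threshold
  if (length(th) != 1L || th <= 0 || th >= 1)
    return("threshold must be a single value in (0, 1)")
  TRUE
})

setMethod("show", "DisorderProfile", function(object) {
  cat(sprintf("DisorderProfile for '%s': %d residues, threshold %.2f\n",
              object@peptide@id, length(object@scores), object@threshold))
  cat(sprintf("  N-terminal disordered prefix: %d residues\n",
              ntermDisorderLength(object)))
})

#' MutationPath: an ordered ladder of helix-stabilizing edits
#'
#' Holds the wildtype peptide and the ordered substitution/insertion steps of a
#' greedy disorder-to-order design, with the predicted helix percentage after
#' each step. Helix percentage is strictly increasing along the path and
#' replaying the edits from the wildtype reproduces each intermediate.
#'
#' @slot wildtype the starting [Peptide-class].
#' @slot steps data.frame with columns kind ("substitution"/"insertion"),
#'   position (1-based index in the sequence the edit produces), from_aa
#'   (NA for insertions), to_aa, sequence (resulting peptide), helix_pct.
#' @slot wildtypeScore helix percentage of the wildtype under the path's scorer.
#' @export
setClass("MutationPath",
         representation(wildtype = "Peptide", steps = "data.frame",
                        wildtypeScore = "numeric"))

setValidity("MutationPath", function(object) {
  st <- object@steps
  need <- c("kind", "position", "from_aa", "to_aa", "sequence", "helix_pct")
  if (!all(need %in% names(st)))
    return(sprintf("steps must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(st)) {
    scores <- c(object@wildtypeScore, st$helix_pct)
    if (any(diff(scores) <= 0))
      return("helix_pct must strictly increase along the path")
    if (any(st$helix_pct < 0 | st$helix_pct > 100))
      return("helix_pct must lie in [0, 100]")
    cur <- object@wildtype@sequence
    for (i in seq_len(nrow(st))) {
      cur <- applyEdit(cur, st$kind[i], st$position[i], st$from_aa[i], st$to_aa[i])
      if (!identical(cur, st$sequence[i]))
        return(sprintf("replaying edits does not reproduce step %d", i))
    }
  }
  TRUE
})

setMethod("show", "MutationPath", function(object) {
  cat(sprintf("MutationPath from '%s' (%d aa, helix%% %.1f): %d step(s)\n",
              object@wildtype@id, nchar(object@wildtype@sequence),
              object@wildtypeScore, nrow(object@steps)))
  if (nrow(object@steps)) {
    st <- object@steps
    lab <- ifelse(st$kind == "insertion",
                  sprintf("ins %s@%d", st$to_aa, st$position),
                  sprintf("%s%d%s", st$from_aa, st$position, st$to_aa))
    cat(sprintf("  step %d: %-9s -> %s  (helix%% %.1f)\n",
                seq_len(nrow(st)), lab, st$sequence, st$helix_pct), sep = "")
  }
})

#' CDSpectrum: a far-UV circular dichroism spectrum
#'
#' Wavelengths (nm, strictly increasing, within 190-250) and mean residue
#' ellipticities in consistent units.
#'
#' @slot wavelengths numeric, nm.
#' @slot ellipticities numeric, same length.
#' @slot id spectrum label.
#' @export
setClass("CDSpectrum",
         representation(wavelengths = "numeric", ellipticities = "numeric",
                        id = "character"))

setValidity("CDSpectrum", function(object) {
  w <- object@wavelengths; e <- object@ellipticities
  if (length(w) < 2L) return("need at least two wavelengths")
  if (length(w) != length(e)) return("wavelengths/ellipticities length mismatch")
  if (any(!is.finite(w)) || any(!is.finite(e))) return("all values must be finite")
  if (any(diff(w) <= 0)) return("wavelengths must be strictly increasing")
  if (min(w) < 190 || max(w) > 250) return("wavelengths must lie within [190, 250] nm")
  TRUE
})

#' @rdname CDSpectrum-class
#' @param wavelengths nm grid.
#' @param ellipticities signal values.
#' @param id label.
#' @export
CDSpectrum <- function(wavelengths, ellipticities, id = "spectrum") {
  new("CDSpectrum", wavelengths = as.numeric(wavelengths),
      ellipticities = as.numeric(ellipticities), id = as.character(id))
}

setMethod("show", "CDSpectrum", function(object) {
  cat(sprintf("CDSpectrum '%s': %d points, %.0f-%.0f nm\n", object@id,
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths)))
})

#' BasisSet: canonical helix/sheet/coil CD basis bands on a shared grid
#'
#' Sign conventions follow the classical far-UV CD signatures: the helix band
#' is positive near 193 nm and negative near 208 and 222 nm; the coil band is
#' negative near 200 nm.
#'
#' @slot grid wavelength grid (nm).
#' @slot bands numeric matrix, one row per grid point, columns H, E, C.
#' @export
setClass("BasisSet",
         representation(grid = "numeric", bands = "matrix"))

setValidity("BasisSet", function(object) {
  g <- object@grid
  b <- object@bands
  if (any(diff(g) <= 0)) return("grid must be strictly increasing")
  if (min(g) < 190 || max(g) > 250) return("grid must lie within [190, 250] nm")
  if (nrow(b) != length(g) || !identical(colnames(b), c("H", "E", "C")))
    return("bands must have one row per grid point and columns H, E, C")
  at <- function(band, nm) stats::approx(g, b[, band], xout = nm, rule = 1)$y
  inr <- function(nm) nm >= min(g) && nm <= max(g)
  if (inr(193) && at("H", 193) <= 0) return("H band must be positive at 193 nm")
  if (inr(208) && at("H", 208) >= 0) return("H band must be negative at 208 nm")
  if (inr(222) && at("H", 222) >= 0) return("H band must be negative at 222 nm")
  if (inr(200) && at("C", 200) >= 0) return("C band must be negative at 200 nm")
  TRUE
})

#' Extract one basis band
#'
#' @param basis a [BasisSet-class].
#' @param state `"H"`, `"E"` or `"C"`.
#' @return numeric band values on the basis grid.
#' @export
basisBand <- function(basis, state = c("H", "E", "C")) {
  state <- match.arg(state)
  basis@bands[, state]
}

setMethod("show", "BasisSet", function(object) {
  cat(sprintf("BasisSet: H/E/C bands on %d-point grid (%.0f-%.0f nm)\n",
              length(object@grid), min(object@grid), max(object@grid)))
})

#' StructureFractions: helix/sheet/coil fractions on the probability simplex
#'
#' @slot fH,fE,fC non-negative fractions summing to 1.
#' @export
setClass("StructureFractions",
         representation(fH = "numeric", fE = "numeric", fC = "numeric"))

setValidity("StructureFractions", function(object) {
  f <- c(object@fH, object@fE, object@fC)
  if (length(f) != 3L || any(!is.finite(f))) return("fractions must be finite scalars")
  if (any(f < -1e-9)) return("fractions must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1 (within 1e-9)")
  TRUE
})

#' @rdname StructureFractions-class
#' @param fH,fE,fC fractions.
#' @export
StructureFractions <- function(fH, fE, fC) {
  new("StructureFractions", fH = as.numeric(fH), fE = as.numeric(fE),
      fC = as.numeric(fC))
}

setMethod("show", "StructureFractions", function(object) {
  cat(sprintf("StructureFractions: fH = %.3f, fE = %.3f, fC = %.3f\n",
              object@fH, object@fE, object@fC))
})

#' CDFit: result of a constrained CD decomposition
#'
#' @slot fractions fitted [StructureFractions-class].
#' @slot residual Euclidean norm of the fit residual.
#' @slot scale fitted positive scale factor (1 when not co-fitted).
#' @export
setClass("CDFit",
         representation(fractions = "StructureFractions", residual = "numeric",
                        scale = "numeric"))

setMethod("show", "CDFit", function(object) {
  f <- object@fractions
  cat(sprintf("CDFit: fH = %.3f, fE = %.3f, fC = %.3f (residual %.4g, scale %.3g)\n",
              f@fH, f@fE, f@fC, object@residual, object@scale))
})

#' SubstitutionModel: reversible amino-acid CTMC for ancestral reconstruction
#'
#' A 20-state continuous-time Markov chain assembled from symmetric
#' exchangeabilities and stationary frequencies, normalized to one expected
#' substitution per site per unit branch length, with an optional global rate
#' factor.
#'
#' @slot Q 20x20 rate matrix (rows sum to zero, off-diagonals non-negative).
#' @slot freqs stationary frequencies (sum to 1, all positive).
#' @slot rate global rate multiplier applied to branch lengths.
#' @slot eig cached eigendecomposition of the symmetrized generator.
#' @export
setClass("SubstitutionModel",
         representation(Q = "matrix", freqs = "numeric", rate = "numeric",
                        eig = "list"))

setValidity("SubstitutionModel", function(object) {
  Q <- object@Q; p <- object@freqs
  if (!all(dim(Q) == c(20L, 20L))) return("Q must be 20x20")
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) return("off-diagonal rates must be non-negative")
  if (any(abs(rowSums(Q)) > 1e-8)) return("rows of Q must sum to 0")
  if (length(p) != 20L || any(p <= 0) || abs(sum(p) - 1) > 1e-8)
    return("freqs must be positive and sum to 1")
  if (length(object@rate) != 1L || object@rate <= 0)
    return("rate must be a positive scalar")
  TRUE
})

setMethod("show", "SubstitutionModel", function(object) {
  cat(sprintf("SubstitutionModel: 20-state reversible CTMC, rate factor %.3g\n",
              object@rate))
})

#' AncestralReconstruction: marginal posteriors and MAP sequences per node
#'
#' @slot tree the rooted input tree (ape phylo).
#' @slot posteriors list, one 20 x n_sites matrix of marginal posteriors per
#'   node (leaves included; leaf posteriors are point masses except at gaps).
#' @slot map named character vector of MAP sequences (aligned coordinates).
#' @slot logLik total log-likelihood of the leaf data.
#' @export
setClass("AncestralReconstruction",
         representation(tree = "ANY", posteriors = "list", map = "character",
                        logLik = "numeric"))

setMethod("show", "AncestralReconstruction", function(object) {
  cat(sprintf("AncestralReconstruction: %d nodes, %d sites, logLik %.3f\n",
              length(object@posteriors),
              ncol(object@posteriors[[1]]), object@logLik))
})

#' CellMask: a binary cell mask
#'
#' A {0,1} pixel grid whose foreground is a single 8-connected component.
#' Pixel side is one unit; indices are R's native 1-based (row, col).
#'
#' @export
setClass("CellMask", contains = "matrix")

setValidity("CellMask", function(object) {
  m <- object@.Data
  if (!all(m %in% c(0, 1))) return("mask values must be 0/1")
  if (sum(m) < 1) return("mask must contain at least one foreground pixel")
  if (countComponents(m) != 1L)
    return("foreground must be a single 8-connected component")
  TRUE
})

#' @rdname CellMask-class
#' @param m 0/1 matrix.
#' @export
CellMask <- function(m) {
  new("CellMask", matrix(as.numeric(m), nrow(m), ncol(m)))
}

setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask: %d x %d grid, %d foreground pixels\n",
              nrow(object), ncol(object), sum(object@.Data)))
})

#' ShmooMeasurement: inscribed-circle morphometry of one cell mask
#'
#' @slot body body circle: list(center = c(row, col), radius).
#' @slot shmoo shmoo circle, or an empty list when no projection was found.
#' @slot length shmoo length in pixels (0 when absent).
#' @slot width shmoo width in pixels (NA when length <= 1).
#' @slot circularFraction fraction of foreground inside the body circle.
#' @slot flags character vector of diagnostic flags.
#' @export
setClass("ShmooMeasurement",
         representation(body = "list", shmoo = "list", length = "numeric",
                        width = "numeric", circularFraction = "numeric",
                        flags = "character"))

setValidity("ShmooMeasurement", function(object) {
  cf <- object@circularFraction
  if (cf < 0 || cf > 1) return("circularFraction must lie in [0, 1]")
  if (object@length < 0) return("length must be non-negative")
  TRUE
})

setMethod("show", "ShmooMeasurement", function(object) {
  cat(sprintf(
    "ShmooMeasurement: body r=%.2f at (%d,%d); shmoo %s; length %.2f px, width %s px; circular fraction %.3f\n",
    object@body$radius, object@body$center[1], object@body$center[2],
    if (length(object@shmoo)) sprintf("r=%.2f", object@shmoo$radius) else "absent",
    object@length,
    if (is.na(object@width)) "NA" else sprintf("%.2f", object@width),
    object@circularFraction))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})
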