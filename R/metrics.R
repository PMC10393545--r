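#' Mutation percentage of a mutant relative to a wildtype
#'
#' The mutation load of a designed peptide: the number of edits
#' (substitutions + insertions) divided by the mutant length, as a percent.
#' The edit list is validated by replaying it: applied in order to the
#' wildtype it must reproduce the mutant exactly.
#'
#' @param wt,mutant [Peptide-class] objects.
#' @param edits data.frame with columns kind ("substitution"/"insertion"),
#'   position (1-based, in the sequence the edit produces), from_aa (NA for
#'   insertions) and to_aa; or a [MutationPath-class], whose steps are used.
#' @return 100 x (number of edits) / nchar(mutant).
#' @examples
#' wt <- Peptide("AAAAAAAAAA")
#' mut <- Peptide("AAAEAAAAAA")
#' edits <- data.frame(kind = "substitution", position = 4,
#'                     from_aa = "A", to_aa = "E")
#' mutationPercent(wt, mut, edits)  # 10
#' @export
mutationPercent <- function(wt, mutant, edits) {
  stopIfNot(is(wt, "Peptide") && is(mutant, "Peptide"),
            "'wt' and 'mutant' must be Peptide objects")
  if (is(edits, "MutationPath")) edits <- edits@steps
  if (nrow(edits) == 0L) {
    if (!identical(wt@sequence, mutant@sequence))
      stop("empty edit list but sequences differ")
    return(0)
  }
  cur <- wt@sequence
  for (i in seq_len(nrow(edits)))
    cur <- applyEdit(cur, edits$kind[i], edits$position[i],
                     edits$from_aa[i], edits$to_aa[i])
  if (!identical(cur, mutant@sequence))
    stop("edit list does not map wildtype to mutant")
  100 * nrow(edits) / nchar(mutant@sequence)
}

#' Per-residue disorder profile of a peptide
#'
#' A windowed propensity profiler standing in for neural disorder predictors:
#' the disorder-propensity value of each residue is averaged over a centered
#' window (truncated, not padded, at the termini) and min-max mapped to
#' [0, 1] using the scale's own extreme values as fixed bounds.
#'
#' @param peptide a [Peptide-class].
#' @param scale disorder propensity scale (default TOP-IDP).
#' @param window odd positive integer window width (default 5).
#' @param threshold disorder call threshold in (0, 1) (default 0.5).
#' @return a [DisorderProfile-class].
#' @export
disorderProfile <- function(peptide, scale = builtinScale("top_idp"),
                            window = 5L, threshold = 0.5) {
  stopIfNot(is(peptide, "Peptide"), "'peptide' must be a Peptide")
  validObject(peptide)
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0)
    stop("'window' must be a positive odd integer")
  raw <- scaleValues(scale, peptide@sequence)
  L <- length(raw)
  half <- (window - 1L) / 2L
  avg <- vapply(seq_len(L), function(i) {
    lo <- max(1L, i - half); hi <- min(L, i + half)
    mean(raw[lo:hi])
  }, 0)
  lo <- min(scale@values); hi <- max(scale@values)
  scores <- (avg - lo) / (hi - lo)
  new("DisorderProfile", scores = scores, threshold = threshold,
      peptide = peptide)
}

#' N-terminal disorder length
#'
#' Length of the maximal N-terminal prefix whose every residue scores at or
#' above the profile threshold; 0 when the first residue is below it.
#'
#' @param profile a [DisorderProfile-class].
#' @return integer number of residues.
#' @export
ntermDisorderLength <- function(profile) {
  stopIfNot(is(profile, "DisorderProfile"), "'profile' must be a DisorderProfile")
  below <- which(profile@scores < profile@threshold)
  if (!length(below)) return(length(profile@scores))
  below[1L] - 1L
}

#' Relative hydrophobicity percent of a peptide
#'
#' Mean hydropathy of the peptide relative to a reference peptide, as a
#' percent. To avoid sign cancellation in the ratio, the hydropathy scale is
#' affine-shifted so its minimum value is 0 before the means are taken; the
#' reference maps to exactly 100.
#'
#' @param peptide,reference [Peptide-class] objects.
#' @param scale hydropathy scale (default Kyte-Doolittle).
#' @return 100 x shifted mean hydropathy(peptide) / shifted mean
#'   hydropathy(reference).
#' @export
hydrophobicityPercent <- function(peptide, reference,
                                  scale = builtinScale("kyte_doolittle")) {
  stopIfNot(is(peptide, "Peptide") && is(reference, "Peptide"),
            "'peptide' and 'reference' must be Peptide objects")
  shift <- min(scale@values)
  mp <- mean(scaleValues(scale, peptide@sequence) - shift)
  mr <- mean(scaleValues(scale, reference@sequence) - shift)
  if (mr == 0)
    stop("degenerate reference: shifted mean hydropathy is 0")
  100 * mp / mr
}
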