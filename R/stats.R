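#' Express values relative to a reference entry, as percent
#'
#' The "relative to reference" normalization used throughout the peptide
#' comparisons (helix%, abundance, hydrophobicity%): each value times 100
#' over the reference value, so the reference maps to exactly 100.
#'
#' @param values named numeric vector.
#' @param referenceId name of the reference entry.
#' @return numeric vector of the same names.
#' @examples
#' relativePercent(c(WT = 2, M4 = 4), "M4")  # WT 50, M4 100
#' @export
relativePercent <- function(values, referenceId) {
  stopIfNot(!is.null(names(values)) && referenceId %in% names(values),
            "'values' must be named and contain the reference id")
  ref <- values[[referenceId]]
  if (ref == 0) stop("degenerate reference: reference value is 0")
  100 * values / ref
}

#' Pearson correlation with contract checks
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return sample correlation in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  stopIfNot(length(x) == length(y), "'x' and 'y' must have equal length")
  stopIfNot(length(x) >= 3, "need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(x, y)
}

#' Pairwise correlation matrix of a three-column measurement table
#'
#' The three-way association among relative helix%, relative abundance and
#' relative hydrophobicity% across peptide variants: a symmetric 3x3 matrix
#' of pairwise correlations with unit diagonal. Spearman is offered alongside
#' Pearson since the underlying relationship is only assumed monotone.
#'
#' @param table data.frame with at least 3 rows; the first three numeric
#'   columns are used (canonically relative_helix_pct, relative_abundance,
#'   relative_hydrophobicity_pct).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric 3x3 correlation matrix.
#' @export
threewayCorrelation <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  num <- table[vapply(table, is.numeric, TRUE)]
  stopIfNot(ncol(num) >= 3, "need three numeric columns")
  num <- num[, 1:3]
  stopIfNot(nrow(num) >= 3, "need at least 3 rows")
  if (any(!is.finite(as.matrix(num)))) stop("all values must be finite")
  for (j in 1:3) if (stats::sd(num[[j]]) == 0)
    stop("undefined correlation: constant column ", names(num)[j])
  m <- stats::cor(num, method = method)
  diag(m) <- 1
  m
}
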