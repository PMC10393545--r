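#' Build canonical helix/sheet/coil CD basis bands on a wavelength grid
#'
#' Each state's band is a sum of Gaussian components
#' `amplitude * exp(-((lambda - center) / width)^2)` with parameters read
#' from a plain-text config (columns: state, center_nm, width_nm, amplitude).
#' The shipped defaults reproduce the classical far-UV signatures: helix
#' positive near 193 nm and negative near 208/222 nm, coil negative near
#' 200 nm. Sign constraints are enforced by the [BasisSet-class] validity.
#'
#' @param grid strictly increasing wavelengths (nm) within [190, 250].
#' @param bandParams data.frame(state, center, width, amplitude) or the path
#'   to a config file; default is the shipped parameterization.
#' @return a [BasisSet-class].
#' @examples
#' b <- makeBasis(seq(190, 250, by = 1))
#' @export
makeBasis <- function(grid, bandParams = tailorderFile("cd_bands.txt")) {
  if (is.character(bandParams)) bandParams <- readBandParams(bandParams)
  need <- c("state", "center", "width", "amplitude")
  stopIfNot(all(need %in% names(bandParams)),
            "bandParams needs columns state, center, width, amplitude")
  stopIfNot(all(bandParams$state %in% c("H", "E", "C")),
            "band states must be H, E or C")
  stopIfNot(all(bandParams$width > 0), "band widths must be positive")
  evalBand <- function(state) {
    rows <- bandParams[bandParams$state == state, , drop = FALSE]
    v <- numeric(length(grid))
    for (i in seq_len(nrow(rows)))
      v <- v + rows$amplitude[i] *
        exp(-((grid - rows$center[i]) / rows$width[i])^2)
    v
  }
  tryCatch(
    new("BasisSet", grid = as.numeric(grid),
        bands = cbind(H = evalBand("H"), E = evalBand("E"),
                      C = evalBand("C"))),
    error = function(e) stop("invalid band configuration: ",
                             conditionMessage(e), call. = FALSE))
}

# Parse the whitespace-separated band config file.
readBandParams <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("state", "center", "width", "amplitude"),
                          stringsAsFactors = FALSE)
  df
}

#' Decompose a CD spectrum into helix/sheet/coil fractions
#'
#' Models the spectrum as a convex combination of the basis bands and
#' minimizes the squared residual over the probability simplex
#' (fH, fE, fC >= 0, fH + fE + fC = 1). With only three states the
#' constrained minimum is found exactly by enumerating the faces of the
#' simplex (interior, three edges, three vertices) and solving each
#' equality-constrained least-squares subproblem in closed form.
#'
#' A spectrum on a different grid is linearly interpolated onto the basis
#' grid; extrapolation is an error. With `fitScale = TRUE` a free positive
#' amplitude is co-fitted (for measured spectra of unknown concentration) by
#' solving the non-negative least-squares problem without the sum constraint
#' and normalizing; the scale is returned alongside.
#'
#' @param spectrum a [CDSpectrum-class].
#' @param basis a [BasisSet-class].
#' @param fitScale co-fit a free positive scale factor (default `FALSE`).
#' @return a [CDFit-class] holding the fractions, the residual norm, and the
#'   fitted scale.
#' @export
fitFractions <- function(spectrum, basis, fitScale = FALSE) {
  stopIfNot(is(spectrum, "CDSpectrum"), "'spectrum' must be a CDSpectrum")
  stopIfNot(is(basis, "BasisSet"), "'basis' must be a BasisSet")
  validObject(spectrum)
  g <- basis@grid
  if (min(spectrum@wavelengths) > min(g) || max(spectrum@wavelengths) < max(g))
    stop("spectrum does not cover the basis grid; extrapolation is forbidden")
  y <- stats::approx(spectrum@wavelengths, spectrum@ellipticities,
                     xout = g, rule = 1)$y
  X <- basis@bands
  if (qr(X)$rank < 3L)
    warning("ill-conditioned (collinear) basis; solution may be non-unique")

  if (fitScale) {
    cf <- nnls3(X, y)
    s <- sum(cf)
    if (s <= 0) stop("degenerate fit: all coefficients zero")
    f <- cf / s
    resid <- sqrt(sum((y - X %*% cf)^2))
    return(new("CDFit",
               fractions = StructureFractions(f[1], f[2], f[3]),
               residual = resid, scale = s))
  }
  f <- simplexLS(X, y)
  resid <- sqrt(sum((y - X %*% f)^2))
  new("CDFit", fractions = StructureFractions(f[1], f[2], f[3]),
      residual = resid, scale = 1)
}

# Exact least squares over the 3-simplex by face enumeration. Each face fixes
# a support S; on S the equality constraint is eliminated by substitution and
# the reduced normal equations solved with a pseudo-inverse (so collinear
# bases degrade gracefully). Deterministic: faces are scanned in a fixed
# order and the first minimum wins.
simplexLS <- function(X, y) {
  best <- NULL; bestRSS <- Inf
  supports <- list(1:3, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1L, 2L, 3L)
  for (S in supports) {
    f <- rep(0, 3)
    if (length(S) == 1L) {
      f[S] <- 1
    } else {
      k <- length(S)
      base <- S[k]
      # f[S[j]] = t_j for j < k, f[base] = 1 - sum t; unconstrained in t
      A <- X[, S[-k], drop = FALSE] - X[, base]
      b <- y - X[, base]
      t <- pinvSolve(A, b)
      f[S[-k]] <- t
      f[base] <- 1 - sum(t)
      if (any(f < -1e-10)) next  # infeasible on this face
      f[f < 0] <- 0
      f <- f / sum(f)
    }
    rss <- sum((y - X %*% f)^2)
    if (rss < bestRSS - 1e-12) { bestRSS <- rss; best <- f }
  }
  best
}

# Non-negative least squares for <= 3 columns by active-set enumeration.
nnls3 <- function(X, y) {
  p <- ncol(X)
  best <- rep(0, p); bestRSS <- sum(y^2)
  subsets <- unlist(lapply(seq_len(p), function(k)
    utils::combn(p, k, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    A <- X[, S, drop = FALSE]
    cf <- pinvSolve(A, y)
    if (any(cf < -1e-10)) next
    cf[cf < 0] <- 0
    full <- rep(0, p); full[S] <- cf
    rss <- sum((y - X %*% full)^2)
    if (rss < bestRSS - 1e-12) { bestRSS <- rss; best <- full }
  }
  best
}

# Minimum-norm least-squares solve via SVD.
pinvSolve <- function(A, b) {
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  dInv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  as.numeric(sv$v %*% (dInv * crossprod(sv$u, b)))
}

#' Relative helix percent of one decomposition against a reference
#'
#' Helix-content ranking used to compare designed peptide variants: the
#' helix fraction of a spectrum decomposition expressed as a percent of a
#' named reference decomposition (which maps to exactly 100).
#'
#' @param f,reference [StructureFractions-class] objects.
#' @return 100 x f\@fH / reference\@fH.
#' @export
relativeHelixPercent <- function(f, reference) {
  stopIfNot(is(f, "StructureFractions") && is(reference, "StructureFractions"),
            "arguments must be StructureFractions")
  if (reference@fH <= 0)
    stop("degenerate reference: helix fraction is 0")
  100 * f@fH / reference@fH
}

#' Read / write a CD spectrum as CSV
#'
#' Two-column CSV with mandatory header `wavelength_nm,ellipticity`.
#'
#' @param path file path.
#' @param id label for the spectrum read.
#' @return [CDSpectrum-class] (read) or the path, invisibly (write).
#' @export
readSpectrumCSV <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "ellipticity") %in% names(df)))
    stop("CSV must have header columns wavelength_nm, ellipticity")
  CDSpectrum(df$wavelength_nm, df$ellipticity, id = id)
}

#' @rdname readSpectrumCSV
#' @param spectrum a [CDSpectrum-class].
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  stopIfNot(is(spectrum, "CDSpectrum"), "'spectrum' must be a CDSpectrum")
  utils::write.csv(data.frame(wavelength_nm = spectrum@wavelengths,
                              ellipticity = spectrum@ellipticities),
                   path, row.names = FALSE)
  invisible(path)
}
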