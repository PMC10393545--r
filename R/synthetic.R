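#' Generate a synthetic shmoo mask with known geometry
#'
#' Rasterizes the union of a disc (the cell body) and a capsule protrusion of
#' half-width `protrusionWidth / 2` extending `protrusionLength` beyond the
#' disc boundary at the given angle, on a grid with at least a 2-pixel
#' background margin. A pixel is foreground iff its center lies inside the
#' continuous shape, so rasterization error stays below half a pixel.
#'
#' Angle convention: 0 points along increasing column, `pi/2` along
#' increasing row.
#'
#' @param bodyRadius disc radius in pixels.
#' @param protrusionLength protrusion extent beyond the disc boundary (px).
#' @param protrusionWidth full protrusion width (px); must be smaller than
#'   the body diameter.
#' @param angle protrusion direction in radians.
#' @param gridSize side of the square grid, or `NULL` to fit automatically.
#' @return list(mask = [CellMask-class], record = ground-truth parameters
#'   including the body center).
#' @export
makeShmooMask <- function(bodyRadius = 20, protrusionLength = 15,
                          protrusionWidth = 7, angle = 0, gridSize = NULL) {
  stopIfNot(bodyRadius > 0, "'bodyRadius' must be positive")
  stopIfNot(protrusionLength >= 0, "'protrusionLength' must be non-negative")
  stopIfNot(protrusionWidth > 0 && protrusionWidth < 2 * bodyRadius,
            "'protrusionWidth' must be positive and smaller than the body diameter")
  reach <- bodyRadius + protrusionLength
  if (is.null(gridSize)) gridSize <- 2L * ceiling(reach) + 7L
  ctr <- (gridSize + 1) / 2
  if (ctr - reach < 3 || ctr + reach > gridSize - 2)
    stop("invalid config: geometry exceeds the grid (need >= 2 px margin)")
  u <- c(sin(angle), cos(angle))                  # (row, col) direction
  rows <- matrix(seq_len(gridSize), gridSize, gridSize)
  cols <- matrix(seq_len(gridSize), gridSize, gridSize, byrow = TRUE)
  dBody <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  # capsule around the segment center -> (reach - width/2) along u, so the
  # rounded cap ends exactly protrusionLength beyond the disc boundary
  segEnd <- max(0, reach - protrusionWidth / 2)
  pr <- rows - ctr; pc <- cols - ctr
  tproj <- pmin(pmax(pr * u[1L] + pc * u[2L], 0), segEnd)
  dSeg <- sqrt((pr - tproj * u[1L])^2 + (pc - tproj * u[2L])^2)
  m <- (dBody <= bodyRadius) | (dSeg <= protrusionWidth / 2)
  mask <- CellMask(m * 1)
  list(mask = mask,
       record = list(bodyRadius = bodyRadius,
                     protrusionLength = protrusionLength,
                     protrusionWidth = protrusionWidth, angle = angle,
                     gridSize = gridSize, center = c(row = ctr, col = ctr)))
}

#' Simulate a noisy CD spectrum from known structure fractions
#'
#' The spectrum is the convex mixture `fH*H + fE*E + fC*C` of the basis
#' bands plus i.i.d. Gaussian noise with standard deviation `noiseSd` times
#' the maximum absolute basis amplitude. Reproducible: the same seed and
#' parameters give bit-identical spectra, and the caller's RNG state is not
#' touched.
#'
#' @param fractions a [StructureFractions-class] (the ground truth).
#' @param basis a [BasisSet-class].
#' @param noiseSd noise level as a fraction of the maximum absolute basis
#'   value; 0 gives the exact mixture.
#' @param seed integer seed.
#' @param id spectrum label.
#' @return list(spectrum = [CDSpectrum-class], record = truth + parameters).
#' @export
simulateCDSpectrum <- function(fractions, basis, noiseSd = 0, seed = 1,
                               id = "synthetic") {
  stopIfNot(is(fractions, "StructureFractions"), "'fractions' must be StructureFractions")
  validObject(fractions)
  stopIfNot(noiseSd >= 0, "'noiseSd' must be non-negative")
  mix <- as.numeric(basis@bands %*% c(fractions@fH, fractions@fE, fractions@fC))
  amp <- max(abs(basis@bands))
  noise <- if (noiseSd > 0)
    withSeed(seed, stats::rnorm(length(mix), sd = noiseSd * amp))
  else rep(0, length(mix))
  list(spectrum = CDSpectrum(basis@grid, mix + noise, id = id),
       record = list(seed = seed, noiseSd = noiseSd,
                     fractions = c(fH = fractions@fH, fE = fractions@fE,
                                   fC = fractions@fC)))
}

#' Evolve a root sequence along a tree (substitution-only)
#'
#' Simulates amino-acid evolution site-independently under the model: on each
#' branch every site is resampled from the row of `P(branch length)` indexed
#' by the parent residue. Returns the leaf alignment (gap-free) and the true
#' sequence at every node, for recovery tests against reconstruction.
#'
#' @param tree rooted ape `phylo` with branch lengths.
#' @param root root sequence ([Peptide-class] or string).
#' @param model a [SubstitutionModel-class].
#' @param seed integer seed.
#' @return list(alignment = named character over leaves, nodeSequences =
#'   named character over all nodes, record).
#' @export
evolveSequences <- function(tree, root, model, seed = 1) {
  if (is(root, "Peptide")) root <- root@sequence
  stopIfNot(is(model, "SubstitutionModel"), "'model' must be a SubstitutionModel")
  rootCodes <- match(strsplit(root, "")[[1]], AMINO_ACIDS)
  stopIfNot(!anyNA(rootCodes), "root sequence must use the 20 canonical amino acids")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tre <- ape::reorder.phylo(tree, "postorder")
  edges <- tre$edge
  elen <- tre$edge.length
  seqs <- vector("list", nnode)
  seqs[[ntip + 1L]] <- rootCodes
  withSeed(seed, {
    for (i in rev(seq_len(nrow(edges)))) {        # preorder: parent before child
      P <- transitionMatrix(model, elen[i])
      parent <- seqs[[edges[i, 1L]]]
      child <- integer(length(parent))
      for (s in unique(parent)) {
        idx <- which(parent == s)
        child[idx] <- sample.int(20L, length(idx), replace = TRUE, prob = P[s, ])
      }
      seqs[[edges[i, 2L]]] <- child
    }
  })
  nn <- nodeNames(tree)
  out <- vapply(seqs, function(cd) paste(AMINO_ACIDS[cd], collapse = ""), "")
  names(out) <- nn
  list(alignment = out[tree$tip.label], nodeSequences = out,
       record = list(seed = seed, rootLength = length(rootCodes)))
}

#' Simulate a peptide family with a disordered N-terminal prefix
#'
#' Emulates the architecture of G-gamma subunits: a root sequence whose first
#' `prefixLen` residues are drawn from a pool of strongly disorder-promoting
#' amino acids (P, E, K, S, Q) and whose `coreLen`-residue body is drawn from
#' an order-promoting pool (W, F, I, L, M, V, Y), then evolved along the
#' tree. The record carries the designed prefix length and the true
#' (simulated) sequence of every node.
#'
#' @param tree rooted ape `phylo` with branch lengths.
#' @param prefixLen designed disordered prefix length (residues).
#' @param coreLen ordered core length (residues, >= 1).
#' @param model a [SubstitutionModel-class].
#' @param seed integer seed.
#' @return list(alignment, nodeSequences, record); record$designedPrefixLen
#'   is the ground truth for N-terminal disorder-length recovery.
#' @export
makeDisorderedFamily <- function(tree, prefixLen = 8, coreLen = 40,
                                 model = substitutionModel(), seed = 1) {
  stopIfNot(prefixLen >= 0, "'prefixLen' must be >= 0")
  stopIfNot(coreLen >= 1, "'coreLen' must be >= 1")
  disorderPool <- c("P", "E", "K", "S", "Q")
  orderPool <- c("W", "F", "I", "L", "M", "V", "Y")
  root <- withSeed(seed, paste(
    c(sample(disorderPool, prefixLen, replace = TRUE),
      sample(orderPool, coreLen, replace = TRUE)), collapse = ""))
  ev <- evolveSequences(tree, root, model, seed = seed + 1L)
  ev$record <- c(ev$record,
                 list(designedPrefixLen = prefixLen, rootSequence = root,
                      familySeed = seed))
  ev
}

#' Random peptide from a residue composition
#'
#' @param length peptide length (>= 1).
#' @param composition named non-negative weights over (a subset of) the 20
#'   amino acids; `NULL` for uniform.
#' @param seed integer seed.
#' @param id label.
#' @return a [Peptide-class].
#' @export
randomPeptide <- function(length, composition = NULL, seed = 1,
                          id = "random") {
  stopIfNot(length >= 1, "'length' must be >= 1")
  if (is.null(composition)) {
    pool <- AMINO_ACIDS
    w <- rep(1, 20)
  } else {
    stopIfNot(all(names(composition) %in% AMINO_ACIDS),
              "composition names must be canonical amino acids")
    stopIfNot(all(composition >= 0) && sum(composition) > 0,
              "composition weights must be non-negative and not all zero")
    pool <- names(composition)
    w <- as.numeric(composition)
  }
  s <- withSeed(seed, paste(sample(pool, length, replace = TRUE, prob = w),
                            collapse = ""))
  Peptide(s, id = id)
}

#' Bivariate table with a target correlation
#'
#' Samples (x, y) from a bivariate normal with correlation `targetR`
#' (`|targetR| = 1` degenerates to an exact linear construction).
#'
#' @param n number of rows.
#' @param targetR target Pearson correlation in [-1, 1].
#' @param seed integer seed.
#' @return data.frame(x, y).
#' @export
makeCorrelatedTable <- function(n, targetR, seed = 1) {
  stopIfNot(abs(targetR) <= 1, "'targetR' must lie in [-1, 1]")
  stopIfNot(n >= 2, "'n' must be >= 2")
  withSeed(seed, {
    x <- stats::rnorm(n)
    z <- stats::rnorm(n)
    y <- targetR * x + sqrt(max(0, 1 - targetR^2)) * z
    data.frame(x = x, y = y)
  })
}
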