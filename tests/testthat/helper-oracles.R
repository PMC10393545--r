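# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive results by brute force or closed form, never by
# calling the code paths they check.

# Exhaustive inscribed-circle search: for every foreground pixel, the
# distance to the nearest background pixel center (the outside of the frame
# counts as background), maximized with the smallest-(row, col) tie rule.
bruteInscribedCircle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  fg <- which(pad > 0, arr.ind = TRUE)
  bg <- which(pad == 0, arr.ind = TRUE)
  best <- -1; bestRC <- NULL
  for (i in seq_len(nrow(fg))) {
    d <- sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
    if (d > best + 1e-12) { best <- d; bestRC <- fg[i, ] }
    else if (abs(d - best) <= 1e-12) {
      cand <- fg[i, ]
      if (cand[1] < bestRC[1] || (cand[1] == bestRC[1] && cand[2] < bestRC[2]))
        bestRC <- cand
    }
  }
  list(center = c(row = unname(bestRC[1]) - 1L, col = unname(bestRC[2]) - 1L),
       radius = best)
}

# Random connected blob mask: union of discs, each overlapping the running
# union, clipped to a size x size grid with a background border.
randomBlobMask <- function(seed, size = 48, discs = 6) {
  set.seed(seed)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  m <- matrix(0, size, size)
  cr <- runif(1, size * 0.3, size * 0.7)
  cc <- runif(1, size * 0.3, size * 0.7)
  for (k in seq_len(discs)) {
    r <- runif(1, 3, size / 5)
    m <- m | (sqrt((rows - cr)^2 + (cols - cc)^2) <= r)
    theta <- runif(1, 0, 2 * pi)
    step <- runif(1, 0, r)
    cr <- min(max(cr + step * sin(theta), 4), size - 3)
    cc <- min(max(cc + step * cos(theta), 4), size - 3)
  }
  m[1, ] <- 0; m[size, ] <- 0; m[, 1] <- 0; m[, size] <- 0
  m * 1
}

# One exhaustive greedy step: materialize every single-substitution (and
# optionally insertion) variant and take the scorer argmax with the
# lowest-position, alphabetical tie rule. Returns NULL at a plateau.
bruteGreedyStep <- function(seq, scorer, currentScore, insertions = FALSE) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  best <- NULL
  consider <- function(variant, pos, aa) {
    s <- scorer(TailOrder::Peptide(variant))
    if (s > currentScore &&
        (is.null(best) || s > best$score ||
         (s == best$score && (pos < best$pos ||
                              (pos == best$pos && aa < best$aa)))))
      best <<- list(variant = variant, score = s, pos = pos, aa = aa)
  }
  if (!insertions) {
    for (pos in seq_len(L)) for (aa in sort(TailOrder::AMINO_ACIDS)) {
      if (aa == chars[pos]) next
      v <- chars; v[pos] <- aa
      consider(paste(v, collapse = ""), pos, aa)
    }
  } else {
    for (pos in seq_len(L + 1L)) for (aa in sort(TailOrder::AMINO_ACIDS))
      consider(paste(append(chars, aa, after = pos - 1L), collapse = ""),
               pos, aa)
  }
  best
}

# Counting scorer used by the greedy-path oracle tests: percent of alanines.
countingScorer <- function(p) {
  chars <- strsplit(p@sequence, "")[[1]]
  100 * sum(chars == "A") / length(chars)
}

# Dense simplex grid search for the CD fit: minimize ||y - X f||^2 over
# f >= 0, sum f = 1, on a regular grid with the given step.
simplexGridSearch <- function(X, y, step = 1e-3) {
  fh <- seq(0, 1, by = step)
  grid <- expand.grid(fH = fh, fE = fh)
  grid <- grid[grid$fH + grid$fE <= 1 + 1e-12, ]
  grid$fC <- pmax(0, 1 - grid$fH - grid$fE)
  G <- crossprod(X)
  cvec <- crossprod(X, y)
  Fm <- as.matrix(grid)
  rss <- rowSums((Fm %*% G) * Fm) - 2 * as.numeric(Fm %*% cvec) + sum(y^2)
  i <- which.min(rss)
  list(f = as.numeric(Fm[i, ]), rss = rss[i])
}

# Closed-form two-leaf marginal root posterior: pi_x P(t1)[x,a] P(t2)[x,b]
# normalized over the 20 root states.
twoLeafRootPosterior <- function(model, t1, t2, a, b) {
  P1 <- TailOrder::transitionMatrix(model, t1)
  P2 <- TailOrder::transitionMatrix(model, t2)
  v <- model@freqs * P1[, a] * P2[, b]
  v / sum(v)
}

# Small balanced tree with constant branch lengths.
balancedTree <- function(nTips, brlen) {
  tr <- ape::stree(nTips, type = "balanced")
  tr$edge.length <- rep(brlen, nrow(tr$edge))
  tr
}
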