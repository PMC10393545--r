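wagModel <- substitutionModel()

test_that("Newick reading validates structure and round-trips", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
  txt <- writeNewick(tr)
  tr2 <- readNewick(txt)
  expect_equal(tr2$tip.label, tr$tip.label)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))
  expect_error(readNewick("((A:1,B:1):1,A:2);"), "duplicate")
  expect_error(readNewick("((A:1,B),C:2);"), "branch length")
})

test_that("annotations survive a Newick write/read round trip", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  ann <- setNames(c(5L, 8L), nodeNames(tr)[4:5])
  txt <- writeNewick(tr, nodeAnnotations = ann)
  back <- readNewick(txt)
  expect_equal(back$node.label, paste0(names(ann), "|", ann))
})

test_that("estimateFrequencies counts residues with pseudocounts", {
  aln <- c(s1 = "AA", s2 = "AL")
  p0 <- estimateFrequencies(aln, 0)
  expect_equal(unname(p0[c("A", "L")]), c(0.75, 0.25))
  expect_equal(sum(p0), 1)
  expect_equal(unname(estimateFrequencies(c(x = "AAAA"), 0)["A"]), 1)
  # huge pseudocount approaches uniform
  pBig <- estimateFrequencies(aln, 1e9)
  expect_equal(unname(pBig), rep(1 / 20, 20), tolerance = 1e-6)
  expect_error(estimateFrequencies(c(x = "--"), 0), "degenerate")
})

test_that("transition matrices satisfy the CTMC laws", {
  m <- wagModel
  expect_equal(transitionMatrix(m, 0), diag(20), ignore_attr = TRUE)
  P1 <- transitionMatrix(m, 0.37)
  expect_true(all(P1 >= 0))
  expect_equal(rowSums(P1), rep(1, 20), ignore_attr = TRUE, tolerance = 1e-9)
  # Chapman-Kolmogorov
  P2 <- transitionMatrix(m, 0.21)
  expect_equal(transitionMatrix(m, 0.58), P1 %*% P2, tolerance = 1e-8)
  # ergodic limit: every row approaches the stationary frequencies
  Pinf <- transitionMatrix(m, 500)
  for (i in c(1, 7, 20))
    expect_equal(unname(Pinf[i, ]), unname(m@freqs), tolerance = 1e-6)
  # rate factor rescales time
  m2 <- substitutionModel(rate = 2)
  expect_equal(transitionMatrix(m2, 0.1), transitionMatrix(m, 0.2),
               tolerance = 1e-10)
  expect_error(transitionMatrix(m, -1), "non-negative")
})

test_that("the model is reversible with the configured frequencies", {
  m <- wagModel
  P <- transitionMatrix(m, 0.5)
  flux <- m@freqs * P                 # flux[i, j] = pi_i P_ij
  expect_equal(flux, t(flux), tolerance = 1e-10,
               ignore_attr = TRUE)    # detailed balance pi_i P_ij = pi_j P_ji
  expect_equal(as.numeric(m@freqs %*% m@Q), rep(0, 20), tolerance = 1e-12)
})

test_that("two-leaf marginal posteriors equal the closed-form enumeration", {
  tr <- readNewick("(A:0.3,B:0.5);")
  cases <- list(c("A", "A"), c("A", "R"), c("W", "C"), c("E", "D"))
  for (cs in cases) {
    aln <- c(A = cs[1], B = cs[2])
    rec <- marginalASR(tr, aln, wagModel)
    oracle <- twoLeafRootPosterior(wagModel, 0.3, 0.5, cs[1], cs[2])
    expect_equal(unname(rec@posteriors[["node3"]][, 1]), unname(oracle),
                 tolerance = 1e-12)
  }
})

test_that("gap columns return the prior and posteriors always sum to one", {
  tr <- readNewick("((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
  aln <- c(A = "A-K", B = "A-R", C = "A-K", D = "A-R")
  rec <- marginalASR(tr, aln, wagModel)
  for (nd in names(rec@posteriors)) {
    expect_equal(colSums(rec@posteriors[[nd]]), rep(1, 3),
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
  # all-gap column: root posterior equals the stationary prior
  expect_equal(unname(rec@posteriors[["node5"]][, 2]), unname(wagModel@freqs),
               tolerance = 1e-9)
})

test_that("identical leaves with near-zero branches pin the ancestral state", {
  tr <- readNewick("((A:1e-8,B:1e-8):1e-8,(C:1e-8,D:1e-8):1e-8);")
  aln <- c(A = "W", B = "W", C = "W", D = "W")
  rec <- marginalASR(tr, aln, wagModel)
  expect_equal(mapSequences(rec)[["node5"]], "W")
  expect_gt(rec@posteriors[["node5"]]["W", 1], 0.999)
})

test_that("tree likelihood is invariant to child traversal order", {
  tr <- readNewick("((A:0.1,B:0.3):0.2,(C:0.15,D:0.25):0.1);")
  trSwap <- readNewick("((D:0.25,C:0.15):0.1,(B:0.3,A:0.1):0.2);")
  aln <- c(A = "ARND", B = "ARNE", C = "GRND", D = "ARKD")
  l1 <- treeLogLik(marginalASR(tr, aln, wagModel))
  l2 <- treeLogLik(marginalASR(trSwap, aln, wagModel))
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("four-leaf posteriors match exhaustive internal-state enumeration", {
  tr <- readNewick("((A:0.1,B:0.3):0.2,(C:0.15,D:0.25):0.1);")
  aln <- c(A = "AR", B = "AR", C = "GR", D = "AK")
  rec <- marginalASR(tr, aln, wagModel)
  P <- function(t) transitionMatrix(wagModel, t)
  P56 <- P(0.2); P6A <- P(0.1); P6B <- P(0.3)
  P57 <- P(0.1); P7C <- P(0.15); P7D <- P(0.25)
  for (site in 1:2) {
    obs <- match(substr(aln, site, site), AMINO_ACIDS)
    post <- matrix(0, 20, 3)   # columns: root(5), node6, node7
    for (x in 1:20) for (y in 1:20) for (z in 1:20) {
      pr <- wagModel@freqs[x] * P56[x, y] * P57[x, z] *
        P6A[y, obs[1]] * P6B[y, obs[2]] * P7C[z, obs[3]] * P7D[z, obs[4]]
      post[x, 1] <- post[x, 1] + pr
      post[y, 2] <- post[y, 2] + pr
      post[z, 3] <- post[z, 3] + pr
    }
    post <- sweep(post, 2, colSums(post), "/")
    for (k in 1:3)
      expect_equal(unname(rec@posteriors[[c("node5", "node6", "node7")[k]]][, site]),
                   post[, k], tolerance = 1e-12)
  }
})

test_that("tree likelihood agrees with phangorn's pruning as an external check", {
  tr <- readNewick("((A:0.1,B:0.3):0.2,(C:0.15,D:0.25):0.1);")
  aln <- c(A = "ARNDC", B = "ARNEC", C = "GRNDW", D = "ARKDC")
  rec <- marginalASR(tr, aln, wagModel)
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  fit <- phangorn::pml(tr, phangorn::phyDat(mat, type = "AA"), model = "WAG")
  expect_equal(treeLogLik(rec), fit$logLik, tolerance = 1e-6)
})

test_that("labels must match between tree and alignment", {
  tr <- readNewick("(A:0.3,B:0.5);")
  expect_error(marginalASR(tr, c(A = "A", X = "R"), wagModel), "labels")
})

test_that("ancestral disorder lengths recover a designed prefix", {
  tr <- balancedTree(8, 0.02)
  fam <- makeDisorderedFamily(tr, prefixLen = 8, coreLen = 40,
                              model = wagModel, seed = 11)
  rec <- marginalASR(tr, fam$alignment, wagModel)
  lens <- annotateDisorderLengths(tr, rec, fam$alignment)
  rootName <- nodeNames(tr)[9]
  expect_lte(abs(lens[[rootName]] - 8), 2)
  # prefix 0 gives disorder length 0 at the root
  fam0 <- makeDisorderedFamily(tr, prefixLen = 0, coreLen = 30,
                               model = wagModel, seed = 12)
  p0 <- disorderProfile(Peptide(fam0$record$rootSequence))
  expect_equal(ntermDisorderLength(p0), 0L)
  # table export
  tab <- disorderLengthTable(lens)
  expect_equal(nrow(tab), 15L)
  expect_true(all(tab$disorder_length >= 0))
})
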