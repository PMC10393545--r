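test_that("distance transform conventions: lone pixel and 3x3 block", {
  # single foreground pixel: distance to the nearest background center is 1
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  circ <- largestInscribedCircle(m)
  expect_equal(circ$radius, 1)
  expect_equal(unname(circ$center), c(3, 3))
  # full-foreground 3x3 grid: the frame edge counts as background, so the
  # middle pixel wins with distance 2 (hand EDT)
  m3 <- matrix(1, 3, 3)
  circ3 <- largestInscribedCircle(m3)
  expect_equal(unname(circ3$center), c(2, 2))
  expect_equal(circ3$radius, 2)
  expect_error(largestInscribedCircle(matrix(0, 3, 3)), "empty mask")
})

test_that("inscribed circle of a rasterized disc recovers center and radius", {
  n <- 41
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  disc <- (sqrt((rows - 21)^2 + (cols - 21)^2) <= 15) * 1
  circ <- largestInscribedCircle(disc)
  expect_lte(max(abs(circ$center - c(21, 21))), 1)
  expect_lte(abs(circ$radius - 15), 1)
})

test_that("inscribed circle equals the exhaustive oracle on random blobs", {
  for (seed in 1:15) {
    m <- randomBlobMask(seed, size = 36)
    got <- largestInscribedCircle(m)
    oracle <- bruteInscribedCircle(m)
    expect_equal(got$radius, oracle$radius, tolerance = 1e-12)
    expect_equal(unname(got$center), unname(oracle$center))
  }
})

test_that("body/shmoo decomposition finds the protrusion", {
  gt <- makeShmooMask(bodyRadius = 15, protrusionLength = 12,
                      protrusionWidth = 7, angle = 0)
  dec <- decomposeBodyShmoo(gt$mask)
  ctr <- gt$record$center
  expect_lte(abs(dec$body$radius - 15), 1)
  expect_lte(max(abs(dec$body$center - ctr)), 1)
  expect_false(is.null(dec$shmoo))
  # shmoo center lies in the protrusion: past the body, along +col
  expect_gt(dec$shmoo$center[2], ctr[2] + 15 - 1)
  expect_lte(abs(dec$shmoo$center[1] - ctr[1]), 4)
  # shmoo circle never overlaps the body circle by construction
  d <- sqrt(sum((dec$shmoo$center - dec$body$center)^2))
  expect_gt(d, dec$body$radius)

  # a pure disc has no (or only crumb-sized) shmoo
  disc <- makeShmooMask(bodyRadius = 15, protrusionLength = 0,
                        protrusionWidth = 5, angle = 0)
  decD <- decomposeBodyShmoo(disc$mask)
  expect_true(is.null(decD$shmoo) || decD$shmoo$radius <= 1)
})

test_that("with two protrusions the shmoo sits in the larger one", {
  g1 <- makeShmooMask(bodyRadius = 14, protrusionLength = 14,
                      protrusionWidth = 9, angle = 0, gridSize = 61)
  g2 <- makeShmooMask(bodyRadius = 14, protrusionLength = 7,
                      protrusionWidth = 5, angle = pi, gridSize = 61)
  m <- pmax(g1$mask@.Data, g2$mask@.Data)
  dec <- suppressMessages(decomposeBodyShmoo(m))
  expect_equal(dec$remainderComponents, 2L)
  # larger protrusion extends along +col from the center
  expect_gt(dec$shmoo$center[2], g1$record$center[2])
})

test_that("shmoo length and width recover generated geometry", {
  for (ang in c(0, pi / 3)) {
    gt <- makeShmooMask(bodyRadius = 20, protrusionLength = 18,
                        protrusionWidth = 7, angle = ang)
    sm <- analyzeMask(gt$mask)
    expect_lte(abs(sm@length - 18), 2)
    expect_lte(abs(sm@width - 7), 2)
  }
  # doubling the scale doubles the measured length within 5%
  a <- analyzeMask(makeShmooMask(12, 10, 5, 0.5)$mask)
  b <- analyzeMask(makeShmooMask(24, 20, 10, 0.5)$mask)
  expect_lt(abs(b@length - 2 * a@length), 0.05 * 2 * a@length + 1e-9)
  # absent shmoo: length 0, width undefined
  disc <- analyzeMask(makeShmooMask(12, 0, 5, 0)$mask)
  expect_equal(disc@length, 0)
  expect_true(is.na(disc@width))
})

test_that("circular fraction matches generated areas and bounds", {
  disc <- makeShmooMask(bodyRadius = 16, protrusionLength = 0,
                        protrusionWidth = 5, angle = 0)
  smD <- analyzeMask(disc$mask)
  expect_gte(smD@circularFraction, 0.95)
  gt <- makeShmooMask(bodyRadius = 16, protrusionLength = 20,
                      protrusionWidth = 8, angle = 1.1)
  sm <- analyzeMask(gt$mask)
  A <- pi * 16^2
  B <- sum(gt$mask@.Data) - A
  expect_lte(abs(sm@circularFraction - A / (A + B)), 0.03)
  expect_true(sm@circularFraction >= 0 && sm@circularFraction <= 1)
})

test_that("rotating a mask by 90 degrees preserves length and width", {
  g0 <- makeShmooMask(bodyRadius = 15, protrusionLength = 14,
                      protrusionWidth = 7, angle = 0)
  g90 <- makeShmooMask(bodyRadius = 15, protrusionLength = 14,
                       protrusionWidth = 7, angle = pi / 2)
  # angle 0 vs pi/2 masks are transposes up to rasterization
  expect_lt(mean(g0$mask@.Data != t(g90$mask@.Data)), 0.01)
  s0 <- analyzeMask(g0$mask); s90 <- analyzeMask(g90$mask)
  expect_lt(abs(s0@length - s90@length), 1)
  expect_lt(abs(s0@width - s90@width), 1)
})

test_that("label images are analyzed per cell with size filtering", {
  lab <- matrix(0L, 60, 130)
  g1 <- makeShmooMask(bodyRadius = 10, protrusionLength = 8,
                      protrusionWidth = 5, angle = 0, gridSize = 45)
  g2 <- makeShmooMask(bodyRadius = 12, protrusionLength = 0,
                      protrusionWidth = 5, angle = 0, gridSize = 45)
  lab[3:47, 3:47][g1$mask@.Data > 0] <- 4L
  lab[3:47, 60:104][g2$mask@.Data > 0] <- 9L
  lab[55, 120] <- 2L                      # 1-pixel debris: skipped
  expect_warning(analyzeLabels(lab), "fewer than")
  tab <- suppressWarnings(analyzeLabels(lab))
  expect_equal(tab$label, c(4L, 9L))
  expect_equal(nrow(tab), 2L)
  # batch equals per-mask analysis
  one <- analyzeMask(g1$mask)
  expect_equal(tab$length_px[1], one@length)
  expect_equal(tab$circular_fraction[1], one@circularFraction)
  # permuting label ids permutes rows but not values
  lab2 <- lab
  lab2[lab == 4L] <- 9L; lab2[lab == 9L] <- 4L
  tab2 <- suppressWarnings(analyzeLabels(lab2))
  expect_equal(tab2$length_px[tab2$label == 9L], tab$length_px[tab$label == 4L])
})

test_that("mask text round trip preserves the grid", {
  gt <- makeShmooMask(bodyRadius = 8, protrusionLength = 6,
                      protrusionWidth = 5, angle = 2)
  f <- withr::local_tempfile(fileext = ".txt")
  writeMaskText(gt$mask@.Data, f)
  back <- readMaskText(f)
  expect_equal(unname(back), unname(gt$mask@.Data))
})

test_that("CellMask validity rejects fragmented foreground", {
  m <- matrix(0, 5, 5); m[1, 1] <- 1; m[5, 5] <- 1
  expect_error(CellMask(m), "single 8-connected")
  m2 <- matrix(0, 5, 5); m2[2, 2] <- 1; m2[3, 3] <- 1   # diagonal touch: ok
  expect_s4_class(CellMask(m2), "CellMask")
})
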