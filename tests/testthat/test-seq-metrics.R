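test_that("Peptide validity enforces the canonical alphabet", {
  expect_s4_class(Peptide("ACDEFGHIKLMNPQRSTVWY"), "Peptide")
  expect_error(Peptide(""), "non-empty")
  expect_error(Peptide("AX-Z"), "invalid residue")
  expect_error(Peptide("AC DE"), "invalid residue")
})

test_that("built-in scales load with one finite value per amino acid", {
  for (nm in c("chou_fasman_alpha", "chou_fasman_beta", "top_idp",
               "kyte_doolittle")) {
    sc <- builtinScale(nm)
    expect_setequal(names(sc@values), AMINO_ACIDS)
    expect_true(all(is.finite(sc@values)))
  }
  # spot values from the published tables
  expect_equal(scaleValues(builtinScale("chou_fasman_alpha"), "E"), 1.51)
  expect_equal(scaleValues(builtinScale("kyte_doolittle"), "R"), -4.5)
})

test_that("peptide FASTA round trip preserves ids and sequences", {
  peps <- list(Peptide("MTSQNKSEPSDGSGK", id = "wt"),
               Peptide("AEALAEAL", id = "helical"))
  f <- withr::local_tempfile(fileext = ".fasta")
  writePeptideFASTA(peps, f)
  back <- readPeptideFASTA(f)
  expect_equal(vapply(back, function(p) p@id, ""), c("wt", "helical"))
  expect_equal(vapply(back, function(p) p@sequence, ""),
               vapply(peps, function(p) p@sequence, ""))
})

test_that("predictSS follows the nucleation/extension rules", {
  # below the 6-residue nucleation window: everything coil
  expect_equal(predictSS(Peptide("A")), "C")
  expect_equal(predictSS(Peptide("AEALA")), "CCCCC")
  # glycine is a helix breaker (P-alpha 0.57): no window can nucleate
  expect_equal(predictSS(Peptide("GGGGGGGGGG")), "CCCCCCCCCC")
  expect_equal(predictSS(Peptide("PPPPPPPP")), "CCCCCCCC")
  # strong formers everywhere: the whole peptide is helix
  expect_equal(predictSS(Peptide("AEALAEALAEALAEAL")),
               strrep("H", 16))
  # output length always matches input length
  for (s in c("MTSQNKSEPSDGSGK", "WYVIT", "KRHDE")) {
    ss <- predictSS(Peptide(s))
    expect_equal(nchar(ss), nchar(s))
    expect_true(grepl("^[HEC]+$", ss))
  }
})

test_that("predictSS is deterministic and sheet segments appear for strand formers", {
  p <- Peptide("MTSQNKSEPSDGSGKVYVIVYVIV")
  expect_identical(predictSS(p), predictSS(p))
  # valine/isoleucine/tyrosine block: strong beta formers, weak helix formers
  ss <- predictSS(Peptide("VYVIVYVIVY"))
  expect_true(grepl("E", ss))
  expect_false(grepl("H", ss))
})

test_that("helixPercent computes 100 * #H / length", {
  expect_equal(helixPercent("CCCC"), 0)
  expect_equal(helixPercent("HHCC"), 50)
  expect_equal(helixPercent("HHHH"), 100)
  expect_equal(helixPercent("HEC"), 100 / 3)
  expect_error(helixPercent(""), "non-empty")
  expect_error(helixPercent("HXC"), "only H, E, C")
})

test_that("mutationPercent validates and counts edits over mutant length", {
  wt <- Peptide("AAAAAAAAAA")
  noEdits <- data.frame(kind = character(), position = integer(),
                        from_aa = character(), to_aa = character())
  expect_equal(mutationPercent(wt, wt, noEdits), 0)
  oneSub <- data.frame(kind = "substitution", position = 4,
                       from_aa = "A", to_aa = "E")
  expect_equal(mutationPercent(wt, Peptide("AAAEAAAAAA"), oneSub), 10)
  # 3 substitutions + 1 insertion on a 10-mer: 4 / 11 edits
  edits <- data.frame(
    kind = c("substitution", "substitution", "substitution", "insertion"),
    position = c(1, 2, 3, 5),
    from_aa = c("A", "A", "A", NA), to_aa = c("E", "E", "E", "W"))
  expect_equal(mutationPercent(wt, Peptide("EEEAWAAAAAA"), edits),
               100 * 4 / 11)
  # inconsistent edit list
  expect_error(mutationPercent(wt, Peptide("AAAAAAAAAC"), oneSub),
               "does not map")
  expect_error(mutationPercent(wt, Peptide("CAAAAAAAAA"), noEdits),
               "sequences differ")
})

test_that("disorderProfile applies truncated windows and fixed scale bounds", {
  sc <- builtinScale("top_idp")
  lo <- min(sc@values); hi <- max(sc@values)
  # window 1: scores are the raw normalized per-residue values
  p <- Peptide("PWE")
  pr <- disorderProfile(p, window = 1)
  expect_equal(pr@scores, (scaleValues(sc, "PWE") - lo) / (hi - lo))
  # homopolymer: constant profile for any window
  pr2 <- disorderProfile(Peptide("EEEEEEEE"), window = 5)
  expect_equal(length(unique(round(pr2@scores, 12))), 1L)
  # hand-computed truncated 5-window average on a 7-mer
  s <- "PEKWFIL"
  raw <- scaleValues(sc, s)
  hand <- c(mean(raw[1:3]), mean(raw[1:4]), mean(raw[1:5]),
            mean(raw[2:6]), mean(raw[3:7]), mean(raw[4:7]), mean(raw[5:7]))
  pr3 <- disorderProfile(Peptide(s), window = 5)
  expect_equal(pr3@scores, (hand - lo) / (hi - lo))
  # invalid windows
  expect_error(disorderProfile(p, window = 4), "odd")
  expect_error(disorderProfile(p, window = 0), "odd|positive")
  # scores always within [0, 1]
  for (seed in 1:5) {
    pp <- randomPeptide(30, seed = seed)
    sc5 <- disorderProfile(pp)@scores
    expect_true(all(sc5 >= 0 & sc5 <= 1))
  }
})

test_that("ntermDisorderLength measures the maximal above-threshold prefix", {
  mk <- function(scores, thr) new("DisorderProfile", scores = scores,
                                  threshold = thr,
                                  peptide = Peptide(strrep("A", length(scores))))
  expect_equal(ntermDisorderLength(mk(c(0.9, 0.8, 0.6, 0.4, 0.7), 0.5)), 3L)
  expect_equal(ntermDisorderLength(mk(rep(0.2, 4), 0.5)), 0L)
  expect_equal(ntermDisorderLength(mk(rep(0.8, 6), 0.5)), 6L)
  # nonincreasing in the threshold
  scores <- c(0.9, 0.7, 0.55, 0.52, 0.3)
  lens <- vapply(c(0.3, 0.5, 0.6, 0.8),
                 function(t) ntermDisorderLength(mk(scores, t)), 0L)
  expect_true(all(diff(lens) <= 0))
})

test_that("hydrophobicityPercent is relative to the reference with shifted scale", {
  m4 <- Peptide("AILAAILV")
  expect_equal(hydrophobicityPercent(m4, m4), 100)
  # mean of identical entries: AAA has shifted mean = KD(A) - min(KD)
  sc <- builtinScale("kyte_doolittle")
  expect_equal(hydrophobicityPercent(Peptide("AAA"), m4),
               100 * (1.8 - (-4.5)) /
                 mean(scaleValues(sc, m4@sequence) - (-4.5)))
  # uniformly less hydrophobic peptide scores below 100
  expect_lt(hydrophobicityPercent(Peptide("SSSSSSSS"), m4), 100)
  # poly-arginine reference has shifted mean exactly 0
  expect_error(hydrophobicityPercent(m4, Peptide("RRRR")),
               "degenerate reference")
})
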