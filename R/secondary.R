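#' Predict per-residue secondary structure of a short peptide
#'
#' Deterministic Chou-Fasman-style nucleation/extension assignment over the
#' three states H (alpha helix), E (extended sheet) and C (random coil).
#'
#' Helix segments nucleate at any 6-residue window containing at least 4
#' residues with P-alpha above the former threshold (default 1.00) and window
#' mean P-alpha above the nucleation mean threshold (default 1.03). Nucleated
#' segments extend residue-by-residue in both directions while the trailing
#' 4-residue mean P-alpha stays at or above 1.00; proline terminates N-ward
#' extension. Sheet segments behave analogously with a 5-residue nucleation
#' window requiring at least 3 formers. Where an H and an E segment overlap,
#' the segment with the larger mean propensity claims the shared residues,
#' with ties going to H. Residues in no segment are C.
#'
#' @param peptide a [Peptide-class].
#' @param alpha helix propensity [PropensityScale-class]
#'   (default Chou-Fasman P-alpha).
#' @param beta sheet propensity scale (default Chou-Fasman P-beta).
#' @param params named list of rule thresholds; any subset of
#'   `helix_window` (6), `helix_min_formers` (4), `helix_former_threshold`
#'   (1.00), `helix_mean_threshold` (1.03), `sheet_window` (5),
#'   `sheet_min_formers` (3), `sheet_former_threshold` (1.00),
#'   `sheet_mean_threshold` (1.03), `extension_window` (4),
#'   `extension_threshold` (1.00).
#' @return single string over \{H, E, C\}, one state per residue.
#' @examples
#' predictSS(Peptide("AEALAEALAEALAEAL"))
#' predictSS(Peptide("GGGGGGGGGG"))
#' @export
predictSS <- function(peptide,
                      alpha = builtinScale("chou_fasman_alpha"),
                      beta = builtinScale("chou_fasman_beta"),
                      params = list()) {
  stopIfNot(is(peptide, "Peptide"), "'peptide' must be a Peptide")
  validObject(peptide)
  p <- utils::modifyList(list(
    helix_window = 6L, helix_min_formers = 4L,
    helix_former_threshold = 1.00, helix_mean_threshold = 1.03,
    sheet_window = 5L, sheet_min_formers = 3L,
    sheet_former_threshold = 1.00, sheet_mean_threshold = 1.03,
    extension_window = 4L, extension_threshold = 1.00), params)

  res <- strsplit(peptide@sequence, "")[[1]]
  L <- length(res)
  pa <- scaleValues(alpha, res)
  pb <- scaleValues(beta, res)

  hseg <- findSegments(res, pa, p$helix_window, p$helix_min_formers,
                       p$helix_former_threshold, p$helix_mean_threshold,
                       p$extension_window, p$extension_threshold,
                       proStopsNterm = TRUE)
  eseg <- findSegments(res, pb, p$sheet_window, p$sheet_min_formers,
                       p$sheet_former_threshold, p$sheet_mean_threshold,
                       p$extension_window, p$extension_threshold,
                       proStopsNterm = FALSE)

  states <- rep("C", L)
  for (s in eseg) states[s$from:s$to] <- "E"
  for (s in hseg) states[s$from:s$to] <- "H"
  # resolve H/E overlaps by the larger segment mean propensity, ties -> H
  for (hs in hseg) for (es in eseg) {
    lo <- max(hs$from, es$from); hi <- min(hs$to, es$to)
    if (lo > hi) next
    hMean <- mean(pa[hs$from:hs$to])
    eMean <- mean(pb[es$from:es$to])
    states[lo:hi] <- if (eMean > hMean) "E" else "H"
  }
  paste(states, collapse = "")
}

# Nucleation + bidirectional extension; returns a list of merged segments
# (from, to). Shared by the helix and sheet rules.
findSegments <- function(res, prop, win, minFormers, formerThr, meanThr,
                         extWin, extThr, proStopsNterm) {
  L <- length(res)
  if (L < win) return(list())
  segs <- list()
  for (i in seq_len(L - win + 1L)) {
    w <- prop[i:(i + win - 1L)]
    if (sum(w > formerThr) >= minFormers && mean(w) > meanThr)
      segs[[length(segs) + 1L]] <- list(from = i, to = i + win - 1L)
  }
  if (!length(segs)) return(list())
  segs <- mergeSegments(segs)
  segs <- lapply(segs, function(s) {
    # C-ward (rightward) extension
    to <- s$to
    while (to < L && mean(prop[(to - extWin + 2L):(to + 1L)]) >= extThr)
      to <- to + 1L
    # N-ward (leftward) extension; proline blocks entry for helices
    from <- s$from
    while (from > 1L &&
           !(proStopsNterm && res[from - 1L] == "P") &&
           mean(prop[(from - 1L):(from + extWin - 2L)]) >= extThr)
      from <- from - 1L
    list(from = from, to = to)
  })
  mergeSegments(segs)
}

mergeSegments <- function(segs) {
  ord <- order(vapply(segs, `[[`, 1L, "from"))
  segs <- segs[ord]
  out <- list(segs[[1L]])
  for (s in segs[-1L]) {
    last <- out[[length(out)]]
    if (s$from <= last$to + 1L) out[[length(out)]]$to <- max(last$to, s$to)
    else out[[length(out) + 1L]] <- s
  }
  out
}

#' Helix percentage of a secondary-structure string
#'
#' @param ss string over \{H, E, C\} as returned by [predictSS()].
#' @return 100 x (number of H residues) / length, in [0, 100].
#' @examples
#' helixPercent("HHCC")  # 50
#' @export
helixPercent <- function(ss) {
  stopIfNot(is.character(ss) && length(ss) == 1L && nzchar(ss),
            "'ss' must be a single non-empty string")
  states <- strsplit(ss, "")[[1]]
  stopIfNot(all(states %in% c("H", "E", "C")),
            "'ss' must contain only H, E, C")
  100 * sum(states == "H") / length(states)
}

#' Helix-percentage scorer for peptides
#'
#' Convenience composition `helixPercent(predictSS(.))` used as the default
#' objective of the greedy mutation-path search.
#'
#' @inheritParams predictSS
#' @return a function mapping a [Peptide-class] to a percent in [0, 100].
#' @export
helixScorer <- function(alpha = builtinScale("chou_fasman_alpha"),
                        beta = builtinScale("chou_fasman_beta"),
                        params = list()) {
  force(alpha); force(beta); force(params)
  function(peptide) helixPercent(predictSS(peptide, alpha, beta, params))
}
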