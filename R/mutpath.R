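#' Enumerate all single-residue substitutions of a peptide
#'
#' @param peptide a [Peptide-class] of length L.
#' @return data.frame with 19 x L rows: position, from_aa, to_aa, variant.
#' @export
enumerateSubstitutions <- function(peptide) {
  stopIfNot(is(peptide, "Peptide"), "'peptide' must be a Peptide")
  chars <- strsplit(peptide@sequence, "")[[1]]
  L <- length(chars)
  rows <- vector("list", 19L * L)
  k <- 0L
  for (pos in seq_len(L)) for (aa in AMINO_ACIDS) {
    if (aa == chars[pos]) next
    v <- chars; v[pos] <- aa
    k <- k + 1L
    rows[[k]] <- data.frame(position = pos, from_aa = chars[pos], to_aa = aa,
                            variant = paste(v, collapse = ""))
  }
  do.call(rbind, rows)
}

#' Enumerate all single-residue insertions into a peptide
#'
#' @param peptide a [Peptide-class] of length L.
#' @return data.frame with 20 x (L + 1) rows: position (index the inserted
#'   residue occupies in the lengthened sequence), to_aa, variant.
#' @export
enumerateInsertions <- function(peptide) {
  stopIfNot(is(peptide, "Peptide"), "'peptide' must be a Peptide")
  chars <- strsplit(peptide@sequence, "")[[1]]
  L <- length(chars)
  rows <- vector("list", 20L * (L + 1L))
  k <- 0L
  for (pos in seq_len(L + 1L)) for (aa in AMINO_ACIDS) {
    v <- append(chars, aa, after = pos - 1L)
    k <- k + 1L
    rows[[k]] <- data.frame(position = pos, from_aa = NA_character_,
                            to_aa = aa, variant = paste(v, collapse = ""))
  }
  do.call(rbind, rows)
}

#' Greedy search for a minimal helix-stabilizing mutation path
#'
#' Emulates iterative single-mutation peptide design: at every iteration all
#' single substitutions are scored and the strictly best one is fixed;
#' when substitutions alone plateau and `allowInsertions` is set, all single
#' insertions are scored and at most one insertion is accepted per plateau
#' event, after which the search returns to substitutions. The search stops
#' when no single edit strictly improves the score (or at `maxSteps`).
#'
#' Ties at the maximum are broken deterministically: lowest position first,
#' then alphabetically earliest target residue (substitutions are preferred
#' over insertions only in the sense that insertions are not examined until
#' substitutions plateau).
#'
#' @param wt wildtype [Peptide-class].
#' @param scorer function mapping a [Peptide-class] to a percent in
#'   [0, 100]; must be deterministic (checked) and total on valid peptides.
#'   Default: [helixScorer()].
#' @param maxSteps maximum number of accepted edits (default `Inf`).
#' @param allowInsertions unlock single insertions at substitution plateaus
#'   (default `TRUE`).
#' @return a [MutationPath-class].
#' @examples
#' countA <- function(p) 100 * lengths(regmatches(p@sequence,
#'   gregexpr("A", p@sequence))) / nchar(p@sequence)
#' greedyHelixPath(Peptide("GGG"), countA, allowInsertions = FALSE)
#' @export
greedyHelixPath <- function(wt, scorer = helixScorer(), maxSteps = Inf,
                            allowInsertions = TRUE) {
  stopIfNot(is(wt, "Peptide"), "'wt' must be a Peptide")
  validObject(wt)
  stopIfNot(is.function(scorer), "'scorer' must be a function")
  stopIfNot(maxSteps >= 1, "'maxSteps' must be >= 1")
  s1 <- scorer(wt); s2 <- scorer(wt)
  if (!identical(s1, s2))
    stop("scorer contract violated: repeated calls on the same peptide differ")

  current <- wt
  currentScore <- s1
  steps <- list()
  repeat {
    if (length(steps) >= maxSteps) break
    subs <- enumerateSubstitutions(current)
    best <- bestVariant(subs, scorer, current@id, currentScore)
    kind <- "substitution"
    if (is.null(best) && allowInsertions) {
      ins <- enumerateInsertions(current)
      best <- bestVariant(ins, scorer, current@id, currentScore)
      kind <- "insertion"
    }
    if (is.null(best)) break
    current <- Peptide(best$variant, id = wt@id)
    currentScore <- best$score
    steps[[length(steps) + 1L]] <- data.frame(
      kind = kind, position = best$position, from_aa = best$from_aa,
      to_aa = best$to_aa, sequence = best$variant, helix_pct = best$score)
  }
  stepDF <- if (length(steps)) do.call(rbind, steps) else
    data.frame(kind = character(), position = integer(),
               from_aa = character(), to_aa = character(),
               sequence = character(), helix_pct = numeric())
  new("MutationPath", wildtype = wt, steps = stepDF, wildtypeScore = s1)
}

# Strictly-improving argmax over an edit table with the deterministic
# tie-break (lowest position, then alphabetical target residue). The table is
# generated in exactly that order, so the first maximum wins.
bestVariant <- function(edits, scorer, id, currentScore) {
  scores <- vapply(edits$variant, function(v) scorer(Peptide(v, id = id)), 0,
                   USE.NAMES = FALSE)
  m <- max(scores)
  if (m <= currentScore) return(NULL)
  i <- which.max(scores)
  list(position = edits$position[i], from_aa = edits$from_aa[i],
       to_aa = edits$to_aa[i], variant = edits$variant[i], score = m)
}

#' Isometric control mutant for a mutation path
#'
#' Builds a control peptide mutated at exactly the same positions (and with
#' insertions mirrored at the same positions) as the helix-stabilizing path,
#' but with control residues chosen by one of two policies:
#' \describe{
#'   \item{C1}{disorder-preserving: at each position, the residue (any of the
#'     19 non-wildtype residues) minimizing the scorer of the cumulative
#'     control sequence.}
#'   \item{C2}{wildtype-like: at each position, the residue from the wildtype
#'     residue's physicochemical class (excluding the wildtype residue
#'     itself) maximizing the scorer. A singleton class is an error.}
#' }
#' Ties are broken alphabetically. For insertions the "wildtype residue" of a
#' C2 step is taken to be the path's inserted residue.
#'
#' @param path a non-empty [MutationPath-class].
#' @param scorer peptide scorer, as in [greedyHelixPath()].
#' @param mode `"C1"` or `"C2"`.
#' @param classes physicochemical partition from [readAAClasses()] (C2 only).
#' @return the control [Peptide-class].
#' @export
isometricControl <- function(path, scorer = helixScorer(),
                             mode = c("C1", "C2"),
                             classes = readAAClasses()) {
  stopIfNot(is(path, "MutationPath"), "'path' must be a MutationPath")
  mode <- match.arg(mode)
  st <- path@steps
  stopIfNot(nrow(st) > 0, "path must contain at least one step")
  classOf <- function(aa) {
    for (cl in classes) if (aa %in% cl) return(cl)
    stop("residue not covered by the class partition: ", aa)
  }
  cur <- path@wildtype@sequence
  for (i in seq_len(nrow(st))) {
    kind <- st$kind[i]; pos <- st$position[i]
    wtRes <- if (kind == "substitution") substr(cur, pos, pos) else st$to_aa[i]
    candidates <- if (mode == "C1") setdiff(AMINO_ACIDS, wtRes)
                  else setdiff(classOf(wtRes), wtRes)
    if (!length(candidates))
      stop(sprintf("no valid C2 control at position %d: class of %s is a singleton",
                   pos, wtRes))
    candidates <- sort(candidates)
    trial <- vapply(candidates, function(aa) {
      s <- applyEdit(cur, kind, pos, NA_character_, aa)
      scorer(Peptide(s, id = path@wildtype@id))
    }, 0)
    pick <- if (mode == "C1") candidates[which.min(trial)]
            else candidates[which.max(trial)]
    cur <- applyEdit(cur, kind, pos, NA_character_, pick)
  }
  Peptide(cur, id = paste0(path@wildtype@id, "_", mode))
}

#' Export a mutation path as a step table
#'
#' @param path a [MutationPath-class].
#' @return data.frame with one row per step: step, kind, position, from, to,
#'   sequence, helix_pct (the layout of the CSV path table).
#' @export
pathTable <- function(path) {
  stopIfNot(is(path, "MutationPath"), "'path' must be a MutationPath")
  st <- path@steps
  data.frame(step = seq_len(nrow(st)), kind = st$kind, position = st$position,
             from = st$from_aa, to = st$to_aa, sequence = st$sequence,
             helix_pct = st$helix_pct)
}
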