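#' Read a rooted Newick tree
#'
#' Wrapper over ape's parser with the validation the reconstruction machinery
#' needs: every edge must carry a finite non-negative branch length and leaf
#' labels must be unique.
#'
#' @param x Newick text or the path to a Newick file.
#' @return an ape `phylo` tree.
#' @export
readNewick <- function(x) {
  tr <- if (length(x) == 1L && file.exists(x) && !grepl("\\(", x))
    ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) stop("malformed Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      any(!is.finite(tr$edge.length)))
    stop("every edge must carry a branch length")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

#' Write a tree to Newick, optionally with per-internal-node annotations
#'
#' Annotations (e.g. disorder lengths) are emitted as internal node labels of
#' the form `name|value`, which survive a write/read round trip.
#'
#' @param tree an ape `phylo`.
#' @param path output file, or `NULL` to return the Newick string.
#' @param nodeAnnotations optional vector named by internal-node names (see
#'   [nodeNames()]).
#' @return the Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, path = NULL, nodeAnnotations = NULL) {
  if (!is.null(nodeAnnotations)) {
    nn <- nodeNames(tree)
    internal <- nn[(length(tree$tip.label) + 1L):length(nn)]
    ann <- nodeAnnotations[internal]
    tree$node.label <- ifelse(is.na(ann), internal,
                              paste0(internal, "|", ann))
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Canonical node names of a tree
#'
#' Tips keep their labels; internal nodes use their `node.label` when present
#' and non-empty, otherwise `node<k>` with k the ape node number.
#'
#' @param tree an ape `phylo`.
#' @return character vector indexed by ape node number.
#' @export
nodeNames <- function(tree) {
  n <- length(tree$tip.label)
  internal <- paste0("node", (n + 1L):(n + tree$Nnode))
  if (!is.null(tree$node.label)) {
    keep <- !is.na(tree$node.label) & nzchar(tree$node.label)
    internal[keep] <- tree$node.label[keep]
  }
  c(tree$tip.label, internal)
}

#' Read a pre-aligned amino-acid FASTA alignment
#'
#' All records must have equal length over the 20 canonical amino acids plus
#' the gap character `-`. Alignment itself is out of scope; this reads the
#' output of an external aligner.
#'
#' @param path FASTA file.
#' @return named character vector of aligned sequences.
#' @export
readAlignmentFASTA <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  aln <- as.character(ss)
  names(aln) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  validateAlignment(aln)
  aln
}

validateAlignment <- function(aln) {
  stopIfNot(length(aln) >= 1L, "alignment is empty")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must have equal length")
  ok <- c(AMINO_ACIDS, "-")
  bad <- setdiff(unique(strsplit(paste(aln, collapse = ""), "")[[1]]), ok)
  if (length(bad))
    stop("alignment alphabet must be the 20 amino acids plus '-'; found: ",
         paste(bad, collapse = ", "))
  invisible(aln)
}

#' Estimate equilibrium amino-acid frequencies from an alignment
#'
#' Normalized residue counts over non-gap characters with an additive
#' pseudocount per amino acid (the "alignment-based background frequency
#' vector" used to reweight the substitution model).
#'
#' @param aln named character vector of aligned sequences (gaps allowed).
#' @param pseudocount additive count per amino acid (default 0).
#' @return named numeric vector over the 20 amino acids, summing to 1.
#' @export
estimateFrequencies <- function(aln, pseudocount = 0) {
  validateAlignment(aln)
  stopIfNot(pseudocount >= 0, "'pseudocount' must be non-negative")
  chars <- strsplit(paste(aln, collapse = ""), "")[[1]]
  chars <- chars[chars != "-"]
  counts <- table(factor(chars, levels = AMINO_ACIDS))
  total <- sum(counts) + 20 * pseudocount
  if (total == 0)
    stop("degenerate input: alignment contains only gaps and pseudocount is 0")
  p <- (as.numeric(counts) + pseudocount) / total
  names(p) <- AMINO_ACIDS
  p
}

#' Assemble a reversible amino-acid substitution model
#'
#' Builds the rate matrix `Q[i, j] = s[i, j] * pi[j]` from symmetric
#' exchangeabilities and stationary frequencies, normalized to one expected
#' substitution per site per unit branch length. The default exchangeability
#' matrix is WAG, shipped as plain-text config; frequencies default to the
#' WAG stationary vector and are typically replaced by
#' [estimateFrequencies()] output (use a positive pseudocount so every
#' frequency is strictly positive).
#'
#' @param rates `"WAG"`, a path to an exchangeability config (lines
#'   `aa1 aa2 rate`), or a symmetric 20x20 matrix with dimnames.
#' @param freqs stationary frequencies (named over the amino acids), or
#'   `NULL` for the model's published frequencies.
#' @param rate global rate factor multiplying all branch lengths (default 1).
#' @return a [SubstitutionModel-class].
#' @export
substitutionModel <- function(rates = "WAG", freqs = NULL, rate = 1) {
  if (is.character(rates)) {
    path <- if (identical(rates, "WAG")) tailorderFile("wag_rates.txt") else rates
    df <- utils::read.table(path, header = FALSE, comment.char = "#",
                            col.names = c("a", "b", "rate"),
                            stringsAsFactors = FALSE)
    S <- matrix(0, 20, 20, dimnames = list(AMINO_ACIDS, AMINO_ACIDS))
    for (i in seq_len(nrow(df))) {
      S[df$a[i], df$b[i]] <- df$rate[i]
      S[df$b[i], df$a[i]] <- df$rate[i]
    }
  } else {
    S <- rates[AMINO_ACIDS, AMINO_ACIDS]
    stopIfNot(isTRUE(all.equal(S, t(S))), "exchangeability matrix must be symmetric")
  }
  if (is.null(freqs)) {
    fd <- utils::read.table(tailorderFile("wag_freqs.txt"), header = FALSE,
                            comment.char = "#", col.names = c("aa", "freq"),
                            stringsAsFactors = FALSE)
    freqs <- stats::setNames(fd$freq, fd$aa)
  }
  if (is.null(names(freqs))) names(freqs) <- AMINO_ACIDS
  p <- freqs[AMINO_ACIDS]
  stopIfNot(all(p > 0), "all stationary frequencies must be strictly positive")
  p <- p / sum(p)
  Q <- S * rep(p, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(p * diag(Q))           # expected substitutions per site per unit time
  Q <- Q / mu
  # symmetrize for a stable, exactly reversible eigendecomposition
  d <- sqrt(p)
  B <- (Q * rep(d, times = 20) / rep(d, each = 20) +
        t(Q * rep(d, times = 20) / rep(d, each = 20))) / 2
  eig <- eigen(B, symmetric = TRUE)
  new("SubstitutionModel", Q = Q, freqs = p, rate = as.numeric(rate),
      eig = list(values = eig$values, vectors = eig$vectors,
                 dPos = d, dNeg = 1 / d))
}

#' Transition probability matrix of a substitution model
#'
#' `P(t) = exp(Q * rate * t)`, computed from the cached eigendecomposition of
#' the reversible generator. Rows sum to 1 and `P(0)` is the identity.
#'
#' @param model a [SubstitutionModel-class].
#' @param t branch length (expected substitutions/site), `t >= 0`.
#' @return 20x20 stochastic matrix with amino-acid dimnames.
#' @export
transitionMatrix <- function(model, t) {
  stopIfNot(is(model, "SubstitutionModel"), "'model' must be a SubstitutionModel")
  stopIfNot(is.numeric(t) && length(t) == 1L && is.finite(t) && t >= 0,
            "'t' must be a single non-negative number")
  e <- model@eig
  expD <- exp(e$values * model@rate * t)
  P <- (e$dNeg * e$vectors) %*% (expD * t(e$vectors)) * rep(e$dPos, each = 20)
  P[P < 0] <- 0
  dimnames(P) <- list(AMINO_ACIDS, AMINO_ACIDS)
  P
}

# Encode an aligned sequence as integer codes 1..20, NA for gaps.
encodeSeq <- function(s) {
  m <- match(strsplit(s, "")[[1]], AMINO_ACIDS)
  m
}

#' Marginal ancestral sequence reconstruction
#'
#' Computes, for every node of a rooted tree and every alignment column, the
#' marginal posterior distribution over the 20 amino acids given the leaf
#' data, by combining upward (Felsenstein pruning) and downward messages.
#' Gaps are treated as missing data (all-ones partial likelihoods), so a
#' column that is gapped everywhere returns the stationary prior. MAP
#' residues break ties alphabetically.
#'
#' @param tree rooted ape `phylo` with branch lengths (see [readNewick()]).
#' @param aln named character vector of aligned sequences; names must match
#'   the tree's leaf labels.
#' @param model a [SubstitutionModel-class].
#' @return an [AncestralReconstruction-class].
#' @export
marginalASR <- function(tree, aln, model) {
  stopIfNot(is(model, "SubstitutionModel"), "'model' must be a SubstitutionModel")
  validateAlignment(aln)
  stopIfNot(ape::is.rooted(tree), "tree must be rooted")
  if (!setequal(tree$tip.label, names(aln)))
    stop("leaf labels of tree and alignment do not match")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  L <- nchar(aln[[1]])
  p <- model@freqs

  tre <- ape::reorder.phylo(tree, "postorder")
  edges <- tre$edge
  elen <- tre$edge.length
  Pmats <- lapply(elen, function(t) transitionMatrix(model, t))

  # upward pass (pruning)
  partial <- vector("list", nnode)
  upMsg <- vector("list", nrow(edges))   # P_e %*% partial[child], per edge
  for (tip in seq_len(ntip)) {
    codes <- encodeSeq(aln[[tree$tip.label[tip]]])
    m <- matrix(0, 20, L)
    obs <- !is.na(codes)
    m[cbind(codes[obs], which(obs))] <- 1
    m[, !obs] <- 1
    partial[[tip]] <- m
  }
  children <- split(seq_len(nrow(edges)), edges[, 1L])
  for (i in seq_len(nrow(edges))) {
    child <- edges[i, 2L]
    parent <- edges[i, 1L]
    upMsg[[i]] <- Pmats[[i]] %*% partial[[child]]
    partial[[parent]] <- if (is.null(partial[[parent]])) upMsg[[i]]
                         else partial[[parent]] * upMsg[[i]]
  }
  # no column rescaling: partial likelihoods stay comfortably within double
  # range at the desk scale this package targets (tens of leaves); guard anyway
  if (any(apply(partial[[root]], 2L, max) < 1e-280))
    stop("numerical underflow in pruning; tree too large for unscaled partials")
  siteL <- colSums(p * partial[[root]])
  logLik <- sum(log(siteL))

  # downward pass
  down <- vector("list", nnode)
  down[[root]] <- matrix(p, 20, L)
  for (i in rev(seq_len(nrow(edges)))) {   # preorder
    parent <- edges[i, 1L]; child <- edges[i, 2L]
    sibEdges <- setdiff(children[[as.character(parent)]], i)
    sib <- matrix(1, 20, L)
    for (j in sibEdges) sib <- sib * upMsg[[j]]
    msg <- down[[parent]] * sib
    d <- crossprod(Pmats[[i]], msg)
    cs <- colSums(d)
    down[[child]] <- sweep(d, 2L, ifelse(cs > 0, cs, 1), "/")
  }

  posteriors <- vector("list", nnode)
  nn <- nodeNames(tree)
  for (v in seq_len(nnode)) {
    post <- down[[v]] * partial[[v]]
    cs <- colSums(post)
    posteriors[[v]] <- sweep(post, 2L, cs, "/")
    rownames(posteriors[[v]]) <- AMINO_ACIDS
  }
  names(posteriors) <- nn
  map <- vapply(posteriors, function(m) {
    paste(apply(m, 2L, function(col) {
      mx <- max(col)
      sort(AMINO_ACIDS[col >= mx - 1e-12])[1L]  # alphabetical tie-break
    }), collapse = "")
  }, "")
  new("AncestralReconstruction", tree = tree, posteriors = posteriors,
      map = map, logLik = logLik)
}

#' Total log-likelihood of leaf data under the model
#'
#' @param rec an [AncestralReconstruction-class].
#' @return log-likelihood accumulated during the pruning pass.
#' @export
treeLogLik <- function(rec) rec@logLik

#' MAP sequences from a reconstruction
#'
#' @param rec an [AncestralReconstruction-class].
#' @param nodes node names (default: all internal nodes).
#' @return named character vector of MAP sequences (aligned coordinates).
#' @export
mapSequences <- function(rec, nodes = NULL) {
  if (is.null(nodes)) {
    ntip <- length(rec@tree$tip.label)
    nodes <- nodeNames(rec@tree)[(ntip + 1L):(ntip + rec@tree$Nnode)]
  }
  rec@map[nodes]
}

#' Annotate every tree node with its N-terminal disorder length
#'
#' For each leaf the aligned sequence is ungapped; for each internal node the
#' reconstruction's MAP sequence is used. Each sequence is profiled with
#' [disorderProfile()] and reduced to its N-terminal disordered prefix length
#' with [ntermDisorderLength()].
#'
#' @param tree rooted ape `phylo`.
#' @param rec matching [AncestralReconstruction-class].
#' @param aln the leaf alignment used for the reconstruction.
#' @param scale,window,threshold passed to [disorderProfile()].
#' @return named integer vector over all node names; exportable through
#'   [writeNewick()] annotations or [disorderLengthTable()].
#' @export
annotateDisorderLengths <- function(tree, rec, aln,
                                    scale = builtinScale("top_idp"),
                                    window = 5L, threshold = 0.5) {
  nn <- nodeNames(tree)
  ntip <- length(tree$tip.label)
  seqs <- character(length(nn)); names(seqs) <- nn
  seqs[tree$tip.label] <- gsub("-", "", aln[tree$tip.label], fixed = TRUE)
  internal <- nn[(ntip + 1L):length(nn)]
  seqs[internal] <- gsub("-", "", rec@map[internal], fixed = TRUE)
  vapply(seqs, function(s) {
    if (!nzchar(s)) {
      warning("empty ungapped sequence; disorder length 0")
      return(0L)
    }
    ntermDisorderLength(disorderProfile(Peptide(s), scale = scale,
                                        window = window, threshold = threshold))
  }, 0L)
}

#' Node-to-disorder-length table
#'
#' @param lengths output of [annotateDisorderLengths()].
#' @return data.frame with columns `node` and `disorder_length`, ready for
#'   CSV export.
#' @export
disorderLengthTable <- function(lengths) {
  data.frame(node = names(lengths), disorder_length = as.integer(lengths),
             row.names = NULL)
}
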