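# Internal helpers shared across modules.

# Apply one edit (substitution or insertion) to a plain sequence string.
# `position` indexes the residue in the sequence the edit produces.
applyEdit <- function(seq, kind, position, from_aa, to_aa) {
  chars <- strsplit(seq, "")[[1]]
  if (kind == "substitution") {
    if (position < 1 || position > length(chars))
      stop("substitution position out of range")
    if (!is.na(from_aa) && chars[position] != from_aa)
      stop(sprintf("edit list inconsistent: expected %s at position %d, found %s",
                   from_aa, position, chars[position]))
    chars[position] <- to_aa
  } else if (kind == "insertion") {
    if (position < 1 || position > length(chars) + 1L)
      stop("insertion position out of range")
    chars <- append(chars, to_aa, after = position - 1L)
  } else stop(sprintf("unknown edit kind '%s'", kind))
  paste(chars, collapse = "")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. All synthetic-data generators funnel through this so
# that every draw is a pure function of (parameters, seed).
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Number of 8-connected foreground components of a 0/1 matrix.
countComponents <- function(m) {
  nrow(labelComponents(m)$sizes)
}

# Label 8-connected foreground components. Returns list(labels = integer
# matrix (0 = background), sizes = data.frame(label, size)).
labelComponents <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  fg <- which(m > 0)
  nextLab <- 0L
  sizes <- integer(0)
  for (start in fg) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- integer(length(fg)); queue[1L] <- start; qhead <- 1L; qtail <- 1L
    lab[start] <- nextLab
    count <- 0L
    while (qhead <= qtail) {
      p <- queue[qhead]; qhead <- qhead + 1L; count <- count + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        p2 <- (c2 - 1L) * nr + r2
        if (m[p2] > 0 && lab[p2] == 0L) {
          lab[p2] <- nextLab
          qtail <- qtail + 1L; queue[qtail] <- p2
        }
      }
    }
    sizes <- c(sizes, count)
  }
  list(labels = lab,
       sizes = data.frame(label = seq_along(sizes), size = sizes))
}

# Path to a shipped config file.
tailorderFile <- function(...) {
  system.file("extdata", ..., package = "TailOrder", mustWork = TRUE)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
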