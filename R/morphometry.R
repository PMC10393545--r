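#' Exact Euclidean distance transform of a binary mask
#'
#' For every foreground pixel, the Euclidean distance to the nearest
#' background pixel center, where everything outside the grid counts as
#' background (the mask is conceptually padded with a ring of zeros). Exact
#' two-pass Felzenszwalb-Huttenlocher algorithm on squared distances.
#' Background pixels get 0; a lone foreground pixel gets 1.
#'
#' @param mask a [CellMask-class] or 0/1 matrix.
#' @return numeric matrix of distances, same shape as the input.
#' @export
distanceTransform <- function(mask) {
  m <- if (is(mask, "CellMask")) mask@.Data else mask
  nr <- nrow(m); nc <- ncol(m)
  # pad with one background ring so the frame edge counts as background
  g <- matrix(0, nr + 2L, nc + 2L)
  g[2:(nr + 1L), 2:(nc + 1L)] <- m
  INF <- (nr + nc + 4)^2
  f <- ifelse(g > 0, INF, 0)
  # pass 1: per column, squared distance along rows
  for (j in seq_len(ncol(f))) f[, j] <- dt1d(f[, j])
  # pass 2: per row
  for (i in seq_len(nrow(f))) f[i, ] <- dt1d(f[i, ])
  sqrt(f[2:(nr + 1L), 2:(nc + 1L)])
}

# 1D squared-distance transform (lower envelope of parabolas).
dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      r <- v[k]
      s <- ((f[q] + q * q) - (f[r] + r * r)) / (2 * q - 2 * r)
      if (s <= z[k]) { k <- k - 1L; next }
      break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    r <- v[k]
    d[q] <- (q - r)^2 + f[r]
  }
  d
}

#' Largest circle inscribed in a binary mask
#'
#' The cell-body primitive: the circle centered at the foreground pixel
#' maximizing the Euclidean distance transform (distance to the nearest
#' background pixel center, with the outside of the frame as background).
#' Ties are broken by the smallest (row, col).
#'
#' @param mask a [CellMask-class] or 0/1 matrix with at least one foreground
#'   pixel.
#' @return list with `center` (integer c(row, col), 1-based) and `radius`
#'   (the EDT value at the center).
#' @export
largestInscribedCircle <- function(mask) {
  m <- if (is(mask, "CellMask")) mask@.Data else mask
  if (sum(m) < 1) stop("empty mask")
  d <- distanceTransform(m)
  best <- max(d)
  hits <- which(d == best, arr.ind = TRUE)
  # smallest (row, col): order by row then col
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  list(center = c(row = unname(hits[1L, 1L]), col = unname(hits[1L, 2L])),
       radius = best)
}

#' Split a cell mask into a body circle and a shmoo circle
#'
#' The body is the largest inscribed circle of the whole mask. The remainder
#' is every foreground pixel whose center lies at distance greater than the
#' body radius from the body center; the shmoo is the largest circle
#' inscribed in the largest 8-connected remainder component (smaller
#' components are ignored with a message). When the remainder is empty the
#' shmoo is absent.
#'
#' @param mask a [CellMask-class] or 0/1 matrix.
#' @return list(body = circle, shmoo = circle or NULL, remainderComponents =
#'   number of remainder components).
#' @export
decomposeBodyShmoo <- function(mask) {
  m <- if (is(mask, "CellMask")) mask@.Data else mask
  body <- largestInscribedCircle(m)
  nr <- nrow(m); nc <- ncol(m)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  distC <- sqrt((rows - body$center[1L])^2 + (cols - body$center[2L])^2)
  remainder <- (m > 0) & (distC > body$radius)
  if (!any(remainder))
    return(list(body = body, shmoo = NULL, remainderComponents = 0L))
  comp <- labelComponents(remainder * 1)
  ncomp <- nrow(comp$sizes)
  if (ncomp > 1L)
    message(sprintf("remainder has %d components; using the largest", ncomp))
  keep <- comp$sizes$label[which.max(comp$sizes$size)]
  sub <- (comp$labels == keep) * 1
  shmoo <- largestInscribedCircle(sub)
  list(body = body, shmoo = shmoo, remainderComponents = ncomp)
}

# Bilinear interpolation of the mask at continuous (row, col); outside the
# grid reads as 0. Foreground is values >= 0.5.
maskAt <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  px <- function(i, j) {
    if (i < 1 || i > nr || j < 1 || j > nc) 0 else m[i, j]
  }
  (1 - fr) * (1 - fc) * px(r0, c0) + (1 - fr) * fc * px(r0, c0 + 1) +
    fr * (1 - fc) * px(r0 + 1, c0) + fr * fc * px(r0 + 1, c0 + 1)
}

# March from `start` along unit direction `u` (step px) while the bilinear
# mask value stays >= 0.5; returns the arc length to the last inside point,
# or NA if the start itself is outside.
marchRay <- function(m, start, u, step = 0.25, tmax = NULL) {
  if (is.null(tmax)) tmax <- ceiling(sqrt(nrow(m)^2 + ncol(m)^2)) + 2
  if (maskAt(m, start[1L], start[2L]) < 0.5) return(NA_real_)
  t <- 0
  while (t + step <= tmax) {
    tn <- t + step
    p <- start + tn * u
    if (maskAt(m, p[1L], p[2L]) < 0.5) break
    t <- tn
  }
  t
}

#' Shmoo length along the body-to-shmoo axis
#'
#' The projection axis is the ray from the body-circle center through the
#' shmoo-circle center. The length runs from the crossing of the body circle
#' boundary to the last foreground point along the ray before the mask is
#' exited (sub-pixel march, 0.25 px steps, bilinear threshold 0.5). The
#' length is 0 when the exit precedes the body boundary.
#'
#' @param mask a [CellMask-class] or 0/1 matrix.
#' @param body,shmoo circles from [decomposeBodyShmoo()].
#' @return list(length, start, end, axis, flag); `length` in pixels.
#' @export
shmooLength <- function(mask, body, shmoo) {
  m <- if (is(mask, "CellMask")) mask@.Data else mask
  if (is.null(shmoo)) return(list(length = 0, start = NULL, end = NULL,
                                  axis = NULL, flag = "no-shmoo"))
  delta <- as.numeric(shmoo$center - body$center)
  nrm <- sqrt(sum(delta^2))
  if (nrm == 0) return(list(length = 0, start = NULL, end = NULL, axis = NULL,
                            flag = "degenerate-axis"))
  u <- delta / nrm
  start <- as.numeric(body$center) + body$radius * u
  t <- marchRay(m, start, u)
  if (is.na(t) || t <= 0)
    return(list(length = 0, start = start, end = start, axis = u,
                flag = if (is.na(t)) "start-outside-mask" else ""))
  list(length = t, start = start, end = start + t * u, axis = u, flag = "")
}

#' Shmoo width perpendicular to the projection axis
#'
#' From the midpoint of the shmoo-line, march perpendicular to the axis in
#' both directions to the mask periphery; the width is the distance between
#' the two crossings. A shmoo must be longer than one pixel to have a width
#' (otherwise `NA`); if only one crossing exists the width is set to 1.
#'
#' @param mask a [CellMask-class] or 0/1 matrix.
#' @param axisInfo result of [shmooLength()].
#' @return width in pixels (NA when length <= 1).
#' @export
shmooWidth <- function(mask, axisInfo) {
  m <- if (is(mask, "CellMask")) mask@.Data else mask
  if (axisInfo$length <= 1) return(NA_real_)
  mid <- (axisInfo$start + axisInfo$end) / 2
  u <- axisInfo$axis
  v <- c(-u[2L], u[1L])
  tPlus <- marchRay(m, mid, v)
  tMinus <- marchRay(m, mid, -v)
  if (is.na(tPlus) || is.na(tMinus)) return(1)   # midpoint on/over the periphery
  w <- tPlus + tMinus
  if (w == 0) 1 else w
}

#' Circular fraction of a mask
#'
#' Fraction of foreground pixels whose centers lie within the body circle;
#' 1 for a perfect disc, decreasing as the projection grows.
#'
#' @param mask a [CellMask-class] or 0/1 matrix.
#' @param body body circle from [largestInscribedCircle()].
#' @return value in [0, 1].
#' @export
circularFraction <- function(mask, body) {
  m <- if (is(mask, "CellMask")) mask@.Data else mask
  nr <- nrow(m); nc <- ncol(m)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  distC <- sqrt((rows - body$center[1L])^2 + (cols - body$center[2L])^2)
  sum(m > 0 & distC <= body$radius) / sum(m > 0)
}

#' Full morphometry of one cell mask
#'
#' Body circle, shmoo circle, shmoo length and width, and circular fraction,
#' bundled as a [ShmooMeasurement-class].
#'
#' @param mask a [CellMask-class] or 0/1 matrix (single 8-connected
#'   component).
#' @return a [ShmooMeasurement-class].
#' @examples
#' gt <- makeShmooMask(bodyRadius = 12, protrusionLength = 8,
#'                     protrusionWidth = 5, angle = 0)
#' analyzeMask(gt$mask)
#' @export
analyzeMask <- function(mask) {
  m <- if (is(mask, "CellMask")) mask@.Data else mask
  dec <- decomposeBodyShmoo(m)
  flags <- character()
  if (dec$remainderComponents > 1L) flags <- c(flags, "multi-component-remainder")
  if (!is.null(dec$shmoo) && dec$shmoo$radius > dec$body$radius)
    flags <- c(flags, "shmoo-larger-than-body")
  li <- shmooLength(m, dec$body, dec$shmoo)
  if (nzchar(li$flag)) flags <- c(flags, li$flag)
  w <- if (is.null(dec$shmoo)) NA_real_ else shmooWidth(m, li)
  new("ShmooMeasurement",
      body = dec$body,
      shmoo = if (is.null(dec$shmoo)) list() else dec$shmoo,
      length = li$length, width = w,
      circularFraction = circularFraction(m, dec$body),
      flags = flags)
}

#' Batch morphometry of a label image
#'
#' Every positive label is analyzed independently as a cell mask (0 =
#' background). Labels with fewer than `minPixels` pixels are skipped with a
#' warning (segmentation debris); a label whose pixels form several
#' 8-connected components is reduced to its largest component with a warning.
#'
#' @param labels integer matrix of non-negative labels.
#' @param minPixels minimum label size in pixels (default 5).
#' @return data.frame, one row per analyzed label: label, body_r, body_row,
#'   body_col, shmoo_r, length_px, width_px, circular_fraction.
#' @export
analyzeLabels <- function(labels, minPixels = 5L) {
  ids <- sort(unique(labels[labels > 0]))
  rows <- list()
  for (id in ids) {
    m <- (labels == id) * 1
    if (sum(m) < minPixels) {
      warning(sprintf("label %d has fewer than %d pixels; skipped", id, minPixels))
      next
    }
    comp <- labelComponents(m)
    if (nrow(comp$sizes) > 1L) {
      warning(sprintf("label %d is not connected; using its largest component", id))
      keep <- comp$sizes$label[which.max(comp$sizes$size)]
      m <- (comp$labels == keep) * 1
    }
    sm <- analyzeMask(m)
    rows[[length(rows) + 1L]] <- data.frame(
      label = id,
      body_r = sm@body$radius,
      body_row = sm@body$center[1L], body_col = sm@body$center[2L],
      shmoo_r = if (length(sm@shmoo)) sm@shmoo$radius else NA_real_,
      length_px = sm@length, width_px = sm@width,
      circular_fraction = sm@circularFraction)
  }
  if (!length(rows))
    return(data.frame(label = integer(), body_r = numeric(),
                      body_row = integer(), body_col = integer(),
                      shmoo_r = numeric(), length_px = numeric(),
                      width_px = numeric(), circular_fraction = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a mask as a plain-text integer matrix
#'
#' Rows of space-separated integers; in a mask any nonzero value is
#' foreground, in a label image values are the labels.
#'
#' @param path file path.
#' @return integer matrix (read) or the path, invisibly (write).
#' @export
readMaskText <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' @rdname readMaskText
#' @param m matrix to write.
#' @export
writeMaskText <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
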