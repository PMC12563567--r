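#' @import methods
#' @importFrom stats rnorm runif rpois median var sd cor aov t.test
#'   wilcox.test kruskal.test pchisq pnorm setNames complete.cases
#' @importFrom utils write.csv read.csv
NULL

# Exact squared Euclidean distance transform (two-pass lower-envelope
# algorithm). `sites` is a logical matrix; the result holds, for every pixel,
# the squared Euclidean distance (an exact integer, stored as double) to the
# nearest TRUE pixel. Exact integer arithmetic is required so that the
# equal-area partition's tie handling is reproducible bit-for-bit.
squaredDistanceTransform <- function(sites) {
  nr <- nrow(sites)
  nc <- ncol(sites)
  # sentinel large enough to dominate any squared pixel distance but small
  # enough that INF + q^2 stays finite and INF - INF is exactly zero
  INF <- 1e30
  f <- matrix(INF, nr, nc)
  f[sites] <- 0

  dt1d <- function(f) {
    n <- length(f)
    d <- numeric(n)
    v <- integer(n)   # parabola sites (1-based)
    z <- numeric(n + 1L)
    k <- 1L
    v[1L] <- 1L
    z[1L] <- -INF
    z[2L] <- INF
    for (q in 2:n) {
      repeat {
        p <- v[k]
        s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * q - 2 * p)
        if (s <= z[k] && k > 1L) {
          k <- k - 1L
        } else {
          break
        }
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- INF
    }
    k <- 1L
    for (q in 1:n) {
      while (z[k + 1L] < q) k <- k + 1L
      p <- v[k]
      d[q] <- (q - p)^2 + f[p]
    }
    d
  }

  # pass 1: along columns; pass 2: along rows
  for (j in seq_len(nc)) {
    col <- f[, j]
    if (any(col == 0)) f[, j] <- dt1d(col)
  }
  g <- matrix(INF, nr, nc)
  for (i in seq_len(nr)) {
    g[i, ] <- dt1d(f[i, ])
  }
  g[g >= INF / 2] <- Inf
  g
}

# 8-connected component labeling: 4-connected labeling (EBImage::bwlabel)
# followed by a union-find merge of diagonally adjacent label pairs.
labelConnected8 <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  l4 <- EBImage::bwlabel(mask)
  l4 <- matrix(as.integer(EBImage::imageData(l4)), nrow(mask), ncol(mask))
  n <- max(l4)
  if (n <= 1L) return(l4)

  parent <- seq_len(n)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nr <- nrow(l4); nc <- ncol(l4)
  collect <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    if (any(keep)) cbind(a[keep], b[keep]) else NULL
  }
  pairs <- rbind(
    collect(l4[-nr, -nc], l4[-1, -1]),   # down-right diagonal
    collect(l4[-nr, -1], l4[-1, -nc])    # down-left diagonal
  )
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    for (i in seq_len(nrow(pairs))) {
      ra <- findRoot(pairs[i, 1L])
      rb <- findRoot(pairs[i, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- l4
  out[out > 0L] <- remap[out[out > 0L]]
  out
}

# Logical disk mask helper used throughout tests and the generator.
diskMask <- function(nrow, ncol, center, radius) {
  rw <- matrix(seq_len(nrow), nrow, ncol)
  cl <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rw - center[1])^2 + (cl - center[2])^2 <= radius^2
}

# Otsu threshold from a pixel-value vector (histogram form). EBImage::otsu
# operates on whole images only, but the threshold here must be computed
# within a mask (e.g. clone cells), so the classic between-class variance
# maximisation is computed directly.
otsuThresholdFromValues <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || length(unique(values)) < 2L) {
    stop("Otsu threshold undefined: fewer than two distinct pixel values")
  }
  lo <- min(values)
  hi <- max(values)
  breaks <- seq(lo, hi, length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  mu <- cumsum(p * mids)
  muT <- mu[levels]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  mids[which.max(sigmaB)]
}

# Bounding box (row/col ranges) of a logical mask, optionally padded.
maskBBox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(
    rows = max(1L, min(idx[, 1]) - pad):min(nrow(mask), max(idx[, 1]) + pad),
    cols = max(1L, min(idx[, 2]) - pad):min(ncol(mask), max(idx[, 2]) + pad)
  )
}
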