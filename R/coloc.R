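#' Structure-level overlap between two channels
#'
#' A structure in the reference channel is double-positive when it shares at
#' least `minSharedPx` pixels with at least one structure of the other
#' channel; the table is computed symmetrically in both directions. The
#' overlap fraction is double-positive count / total count of the reference
#' (first) channel.
#'
#' @param a,b [StructureSet-class] objects from the same cell (same shape).
#' @param minSharedPx integer(1), minimum shared pixels to count as overlap
#'   (default 1: any shared pixel).
#' @return list with `overlapAB`, `overlapBA` (data.frames: structure id,
#'   partner ids, shared px), `doublePositiveA`, `doublePositiveB`,
#'   `singlePositiveA`, `singlePositiveB`, `totalA`, `totalB`,
#'   `overlapFraction`.
#' @export
structureOverlap <- function(a, b, minSharedPx = 1L) {
  stopifnot(is(a, "StructureSet"), is(b, "StructureSet"))
  if (!identical(dim(a@labelMap), dim(b@labelMap))) {
    stop("label maps differ in shape")
  }
  la <- a@labelMap
  lb <- b@labelMap
  both <- la > 0L & lb > 0L
  pairTable <- if (any(both)) {
    tab <- table(A = la[both], B = lb[both])
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df <- df[df$Freq >= minSharedPx, ]
    data.frame(a = as.integer(df$A), b = as.integer(df$B),
               shared_px = as.integer(df$Freq))
  } else {
    data.frame(a = integer(), b = integer(), shared_px = integer())
  }
  overlapAB <- data.frame(
    structure = a@stats$label,
    n_partners = vapply(a@stats$label,
                        function(l) sum(pairTable$a == l), integer(1)),
    shared_px = vapply(a@stats$label,
                       function(l) sum(pairTable$shared_px[pairTable$a == l]),
                       integer(1)))
  overlapBA <- data.frame(
    structure = b@stats$label,
    n_partners = vapply(b@stats$label,
                        function(l) sum(pairTable$b == l), integer(1)),
    shared_px = vapply(b@stats$label,
                       function(l) sum(pairTable$shared_px[pairTable$b == l]),
                       integer(1)))
  dpA <- sum(overlapAB$n_partners > 0L)
  dpB <- sum(overlapBA$n_partners > 0L)
  totalA <- nrow(a@stats)
  totalB <- nrow(b@stats)
  list(cellId = a@cellId,
       channels = c(a@channel, b@channel),
       pairs = pairTable,
       overlapAB = overlapAB, overlapBA = overlapBA,
       doublePositiveA = dpA, doublePositiveB = dpB,
       singlePositiveA = totalA - dpA, singlePositiveB = totalB - dpB,
       totalA = totalA, totalB = totalB,
       overlapFraction = if (totalA > 0) dpA / totalA else NA_real_)
}

#' Remove double-positive (overlapping) structures from both channels
#'
#' Deletes every structure that overlaps (>= `minSharedPx` shared pixels) a
#' structure of the other channel, from both sets, leaving the
#' non-colocalizing structures — the input expected by the distribution
#' index when scoring each marker's own population. Re-running
#' [structureOverlap()] on the outputs reports zero double-positives.
#'
#' @inheritParams structureOverlap
#' @return list of the two pruned [StructureSet-class] objects (`a`, `b`).
#' @export
removeOverlapping <- function(a, b, minSharedPx = 1L) {
  ov <- structureOverlap(a, b, minSharedPx = minSharedPx)
  prune <- function(s, dropLabels) {
    lm <- s@labelMap
    lm[lm %in% dropLabels] <- 0L
    present <- sort(unique(lm[lm > 0L]))
    if (length(present)) lm[lm > 0L] <- match(lm[lm > 0L], present)
    keep <- !(s@stats$label %in% dropLabels)
    st <- s@stats[keep, , drop = FALSE]
    if (nrow(st)) {
      st$label <- match(st$label, s@stats$label[keep]) # consecutive again
      st$label <- seq_len(nrow(st))
    }
    rownames(st) <- NULL
    new("StructureSet", cellId = s@cellId, channel = s@channel,
        labelMap = lm, stats = st, minSizePx = s@minSizePx)
  }
  dropA <- ov$overlapAB$structure[ov$overlapAB$n_partners > 0L]
  dropB <- ov$overlapBA$structure[ov$overlapBA$n_partners > 0L]
  list(a = prune(a, dropA), b = prune(b, dropB))
}

#' Pixel-wise Pearson correlation between two channels
#'
#' Product-moment correlation of raw intensities over the cytoplasmic
#' pixels of one cell (no thresholding), with the per-pixel intensity pairs
#' returned for scatter plots. Optional constant-background subtraction.
#' Zero variance in either channel yields a flagged-undefined result.
#'
#' @param scene a [TissueScene-class].
#' @param roi a [CellROI-class].
#' @param roles character(2), the channel pair.
#' @param subtractBackground logical(1); when TRUE, each channel's modal
#'   (minimum) cytoplasmic intensity is subtracted before correlating
#'   (affects the scatter pairs, not R).
#' @return list with `R`, `defined`, `n` (pixel count) and `scatter`
#'   (data.frame with one intensity pair per cytoplasmic pixel).
#' @export
pixelPearson <- function(scene, roi, roles, subtractBackground = FALSE) {
  stopifnot(is(scene, "TissueScene"), is(roi, "CellROI"),
            length(roles) == 2L)
  cyto <- which(cytoplasmMask(roi))
  if (length(cyto) < 2L) stop("cytoplasm must hold at least 2 pixels")
  x <- getChannel(scene, roles[1])[cyto]
  y <- getChannel(scene, roles[2])[cyto]
  if (subtractBackground) {
    x <- x - min(x)
    y <- y - min(y)
  }
  defined <- var(x) > 0 && var(y) > 0
  list(R = if (defined) cor(x, y) else NA_real_,
       defined = defined,
       n = length(cyto),
       scatter = data.frame(intensity_a = x, intensity_b = y))
}

#' Average pixel Pearson coefficient over a set of cells
#'
#' @param scene a [TissueScene-class].
#' @param rois list of [CellROI-class].
#' @param roles character(2), the channel pair.
#' @return list with `meanR`, `perCell` (data.frame cell_id, R, n).
#' @export
averagePearson <- function(scene, rois, roles) {
  perCell <- do.call(rbind, lapply(rois, function(r) {
    p <- pixelPearson(scene, r, roles)
    data.frame(cell_id = r@cellId,
               R = if (p$defined) p$R else NA_real_, n = p$n)
  }))
  list(meanR = mean(perCell$R, na.rm = TRUE), perCell = perCell)
}
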