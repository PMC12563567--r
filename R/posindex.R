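#' Partition a cell's cytoplasm into equal-area perinuclear and peripheral
#' domains
#'
#' Every cytoplasmic pixel is ranked by its exact Euclidean distance to the
#' nucleus mask (distance to the nearest nucleus pixel, computed on integer
#' squared distances so ties are exact). The half-area rank defines the split
#' distance d*: pixels closer than d* are perinuclear, pixels farther are
#' peripheral, and pixels exactly at d* are assigned in deterministic
#' raster order (row-major) to the perinuclear domain until it reaches
#' ceiling(area/2), the remainder going to the peripheral domain. The two
#' domain areas therefore differ by at most 1 px for any cell shape.
#'
#' @param roi a [CellROI-class] with a non-empty nucleus.
#' @return a [DomainPartition-class].
#' @examples
#' roi <- diskCellROI(nrow = 121, ncol = 121, cellRadius = 55,
#'                    nucleusRadius = 12)
#' part <- equalAreaPartition(roi)
#' splitDistance(part)
#' @export
equalAreaPartition <- function(roi) {
  stopifnot(is(roi, "CellROI"))
  if (!any(roi@nucleusMask)) {
    stop("cell ", roi@cellId,
         ": partition undefined without a nucleus reference (empty nucleus mask)")
  }
  cyto <- roi@cellMask & !roi@nucleusMask
  n <- sum(cyto)
  if (n == 0L) stop("cell ", roi@cellId, ": cytoplasm is empty")

  # work on a padded bounding box to keep the distance transform cheap
  bb <- maskBBox(roi@cellMask, pad = 1L)
  d2full <- matrix(NA_real_, nrow(cyto), ncol(cyto))
  d2full[bb$rows, bb$cols] <-
    squaredDistanceTransform(roi@nucleusMask[bb$rows, bb$cols, drop = FALSE])

  idx <- which(cyto)                      # column-major linear indices
  d2 <- d2full[idx]
  rows <- ((idx - 1L) %% nrow(cyto)) + 1L
  cols <- ((idx - 1L) %/% nrow(cyto)) + 1L
  ord <- order(d2, rows, cols)            # distance, then raster (row-major)

  target <- as.integer(ceiling(n / 2))
  periIdx <- idx[ord[seq_len(target)]]
  peri <- matrix(FALSE, nrow(cyto), ncol(cyto))
  peri[periIdx] <- TRUE
  periph <- cyto & !peri

  new("DomainPartition",
      cellId = roi@cellId,
      perinuclear = peri,
      peripheral = periph,
      splitDistance = sqrt(d2[ord[target]]),
      areaDifference = abs(target - (n - target)))
}

#' Signed perinuclear distribution index of a signal mask
#'
#' Computes D = (A_peri - A_periph) / A_total, where A_peri and A_periph are
#' the areas (pixel counts) of the thresholded signal falling in the
#' perinuclear and peripheral domains and A_total is the signal area over
#' the whole cytoplasm. D is +1 when all signal is perinuclear, 0 when the
#' signal is evenly dispersed, and -1 when all signal is peripheral. The
#' signal mask is clipped to the cytoplasm (the union of the two domains)
#' before counting, so A_peri + A_periph = A_total always holds. A cell
#' without signal yields a flagged-undefined result, not an error.
#'
#' @param partition a [DomainPartition-class].
#' @param signalMask logical or 0/1 matrix of above-threshold signal.
#' @param channel character(1), channel role recorded in the result.
#' @return a [DistributionResult-class].
#' @examples
#' roi <- diskCellROI(121, 121, 55, 12)
#' part <- equalAreaPartition(roi)
#' res <- distributionIndex(part, perinuclearMask(part))
#' indexValue(res)   # exactly 1
#' @export
distributionIndex <- function(partition, signalMask, channel = "puncta-A") {
  stopifnot(is(partition, "DomainPartition"))
  signalMask <- signalMask != 0
  if (!identical(dim(signalMask), dim(partition@perinuclear))) {
    stop("signal mask shape does not match the partition")
  }
  aPeri <- sum(signalMask & partition@perinuclear)
  aPeriph <- sum(signalMask & partition@peripheral)
  aTotal <- aPeri + aPeriph
  new("DistributionResult",
      cellId = partition@cellId,
      channel = channel,
      APeri = as.numeric(aPeri),
      APeriph = as.numeric(aPeriph),
      ATotal = as.numeric(aTotal),
      D = if (aTotal > 0) (aPeri - aPeriph) / aTotal else NA_real_,
      defined = aTotal > 0)
}

#' Default thresholds for localization phenotype calls
#'
#' All four decision parameters are free, configurable choices (the original
#' phenotype calls were made by eye): `DHi`/`DLo` bound the index for the
#' perinuclear/peripheral calls; a cell is called `ectopic_focus` when the
#' largest single-linkage cluster of structure centroids (linking radius
#' `linkRadiusUm`) holds at least `clusterFraction` of the total structure
#' area and its area-weighted centroid lies farther than `offsetUm` from the
#' nucleus boundary.
#'
#' @param DHi,DLo index bounds for perinuclear / peripheral calls.
#' @param clusterFraction minimum area fraction of the dominant cluster.
#' @param offsetUm minimum distance (um) of the dominant cluster centroid
#'   from the nucleus boundary.
#' @param linkRadiusUm single-linkage linking radius (um).
#' @return a named list of thresholds.
#' @export
localizationThresholds <- function(DHi = 0.5, DLo = -0.5,
                                   clusterFraction = 0.5, offsetUm = 10,
                                   linkRadiusUm = 5) {
  list(DHi = DHi, DLo = DLo, clusterFraction = clusterFraction,
       offsetUm = offsetUm, linkRadiusUm = linkRadiusUm)
}

#' Classify the localization phenotype of one cell
#'
#' Automated surrogate for manual phenotype counts: a cell is
#' `ectopic_focus` when most of its structure area sits in one tight
#' cluster away from the nucleus (see [localizationThresholds()]);
#' otherwise the distribution index decides between `perinuclear`
#' (D >= DHi), `peripheral` (D <= DLo) and `dispersed`.
#'
#' @param result a [DistributionResult-class] for the cell.
#' @param structures a [StructureSet-class] for the same cell/channel.
#' @param roi the [CellROI-class].
#' @param pixelSizeUm numeric(1), micrometres per pixel.
#' @param thresholds list from [localizationThresholds()].
#' @return list with `category` (one of "perinuclear", "dispersed",
#'   "peripheral", "ectopic_focus") and the supporting numbers
#'   (`D`, `clusterFraction`, `clusterDistanceUm`).
#' @export
classifyLocalization <- function(result, structures, roi, pixelSizeUm,
                                 thresholds = localizationThresholds()) {
  stopifnot(is(result, "DistributionResult"), is(structures, "StructureSet"),
            is(roi, "CellROI"))
  st <- structures@stats
  clusterFraction <- NA_real_
  clusterDistanceUm <- NA_real_
  isEctopic <- FALSE

  if (nrow(st) >= 1L) {
    cent <- cbind(st$centroid_row, st$centroid_col) * pixelSizeUm
    if (nrow(st) == 1L) {
      membership <- 1L
    } else {
      hc <- stats::hclust(stats::dist(cent), method = "single")
      membership <- stats::cutree(hc, h = thresholds$linkRadiusUm)
    }
    areaByCluster <- tapply(st$area_px, membership, sum)
    dominant <- as.integer(names(which.max(areaByCluster)))
    clusterFraction <- max(areaByCluster) / sum(st$area_px)
    inDom <- membership == dominant
    w <- st$area_px[inDom]
    cRow <- sum(st$centroid_row[inDom] * w) / sum(w)
    cCol <- sum(st$centroid_col[inDom] * w) / sum(w)
    # distance of the cluster centroid to the nucleus boundary
    bb <- maskBBox(roi@cellMask, pad = 1L)
    d2 <- squaredDistanceTransform(roi@nucleusMask[bb$rows, bb$cols,
                                                   drop = FALSE])
    r <- min(max(1L, round(cRow) - bb$rows[1] + 1L), nrow(d2))
    cc <- min(max(1L, round(cCol) - bb$cols[1] + 1L), ncol(d2))
    clusterDistanceUm <- sqrt(d2[r, cc]) * pixelSizeUm
    isEctopic <- clusterFraction >= thresholds$clusterFraction &&
      clusterDistanceUm > thresholds$offsetUm
  }

  D <- indexValue(result)
  category <- if (isEctopic) {
    "ectopic_focus"
  } else if (!is.na(D) && D >= thresholds$DHi) {
    "perinuclear"
  } else if (!is.na(D) && D <= thresholds$DLo) {
    "peripheral"
  } else {
    "dispersed"
  }
  list(cellId = roi@cellId, category = category, D = D,
       clusterFraction = clusterFraction,
       clusterDistanceUm = clusterDistanceUm)
}

#' Per-cell distribution-index table for a cohort of clone cells
#'
#' Runs QC, the equal-area partition, channel thresholding and the
#' distribution index for every clone-positive cell and returns one row per
#' eligible cell. Cells with an undefined index (no above-threshold signal)
#' are excluded and reported via `message()`.
#'
#' @param scene a [TissueScene-class].
#' @param rois list of [CellROI-class].
#' @param channel character(1), puncta channel role.
#' @param threshold numeric threshold or "auto" (Otsu within the cell); see
#'   [thresholdChannel()].
#' @param cloneOnly logical(1), restrict to clone-positive cells (default).
#' @return data.frame with columns `cell_id`, `A_peri`, `A_periph`,
#'   `A_total`, `D`, `clone`, `tissue_edge`.
#' @export
cohortIndexTable <- function(scene, rois, channel, threshold = "auto",
                             cloneOnly = TRUE) {
  stopifnot(is(scene, "TissueScene"))
  keep <- qcCells(rois)
  if (cloneOnly) keep <- Filter(cloneStatus, keep)
  if (length(keep) == 0L) stop("no eligible cells (after QC/clone filter)")
  rows <- lapply(keep, function(roi) {
    part <- equalAreaPartition(roi)
    sig <- thresholdChannel(scene, channel, roi, threshold = threshold)
    res <- distributionIndex(part, sig, channel = channel)
    if (!res@defined) {
      message("cell ", roi@cellId, ": no signal above threshold; excluded")
      return(NULL)
    }
    data.frame(cell_id = roi@cellId, A_peri = res@APeri,
               A_periph = res@APeriph, A_total = res@ATotal, D = res@D,
               clone = roi@cloneStatus, tissue_edge = roi@tissueEdge)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stop("no eligible cells (all had zero signal)")
  do.call(rbind, rows)
}

#' Construct a disk-shaped test cell
#'
#' Convenience constructor for analytic checks: a disk cell of radius
#' `cellRadius` with a concentric disk nucleus of radius `nucleusRadius`,
#' centred in the field. For such a cell the continuum equal-area split
#' radius is sqrt((R^2 + r^2) / 2).
#'
#' @param nrow,ncol field size in pixels.
#' @param cellRadius,nucleusRadius disk radii in pixels.
#' @param cellId integer id.
#' @param center optional (row, col) centre; defaults to the field centre.
#' @return a [CellROI-class].
#' @export
diskCellROI <- function(nrow, ncol, cellRadius, nucleusRadius,
                        cellId = 1L, center = NULL) {
  if (is.null(center)) center <- c((nrow + 1) / 2, (ncol + 1) / 2)
  new("CellROI",
      cellId = as.integer(cellId),
      cellMask = diskMask(nrow, ncol, center, cellRadius),
      nucleusMask = diskMask(nrow, ncol, center, nucleusRadius),
      cloneStatus = TRUE, tissueEdge = FALSE, nucleusInPlane = TRUE)
}
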