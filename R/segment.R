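#' Threshold one channel within a cell
#'
#' Pixels strictly above the threshold, intersected with the cell mask;
#' nucleus pixels are excluded by default because the distribution index is
#' defined on the cytoplasm. The threshold is a single global value per
#' channel per experiment; `"auto"` computes an Otsu threshold from the
#' pixel values inside the cell mask.
#'
#' @param scene a [TissueScene-class].
#' @param role channel role.
#' @param roi a [CellROI-class].
#' @param threshold numeric(1) >= 0, or "auto" for Otsu within the cell.
#' @param excludeNucleus logical(1), drop nucleus pixels (default TRUE).
#' @return logical matrix.
#' @export
thresholdChannel <- function(scene, role, roi, threshold = "auto",
                             excludeNucleus = TRUE) {
  stopifnot(is(scene, "TissueScene"), is(roi, "CellROI"))
  ch <- getChannel(scene, role)
  region <- if (excludeNucleus) cytoplasmMask(roi) else roi@cellMask
  if (!any(region)) stop("cell ", roi@cellId, ": empty ROI")
  if (identical(threshold, "auto")) {
    threshold <- otsuThresholdFromValues(ch[roi@cellMask])
  } else if (!is.numeric(threshold) || length(threshold) != 1L ||
             threshold < 0) {
    stop("threshold must be a single value >= 0, or \"auto\"")
  }
  (ch > threshold) & region
}

# per-structure statistics for a label map
structureStats <- function(labels, intensity, pixelSizeUm) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), centroid_row = numeric(),
                      centroid_col = numeric(), mean_intensity = numeric(),
                      bbox_rmin = integer(), bbox_rmax = integer(),
                      bbox_cmin = integer(), bbox_cmax = integer()))
  }
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  vals <- intensity[idx]
  byLab <- function(x, f) as.numeric(tapply(x, lab, f))
  u <- sort(unique(lab))
  data.frame(
    label = as.integer(u),
    area_px = as.integer(byLab(rows, length)),
    area_um2 = byLab(rows, length) * pixelSizeUm^2,
    centroid_row = byLab(rows, mean),
    centroid_col = byLab(cols, mean),
    mean_intensity = byLab(vals, mean),
    bbox_rmin = as.integer(byLab(rows, min)),
    bbox_rmax = as.integer(byLab(rows, max)),
    bbox_cmin = as.integer(byLab(cols, min)),
    bbox_cmax = as.integer(byLab(cols, max)))
}

#' Label connected structures within a thresholded mask
#'
#' 8-connected component labeling of the above-threshold foreground, with
#' components smaller than `minSizePx` discarded (single-pixel noise
#' suppression) and per-structure statistics computed.
#'
#' @param mask logical matrix from [thresholdChannel()] (or any binary
#'   mask within one cell).
#' @param scene optional [TissueScene-class] for mean intensities.
#' @param roi the owning [CellROI-class].
#' @param channel channel role recorded (and used for intensities when
#'   `scene` is given).
#' @param minSizePx integer(1), minimum structure area (default 4 px).
#' @param labels optional precomputed label map (e.g. from
#'   [splitTouching()]); when supplied, `mask` is ignored.
#' @return a [StructureSet-class].
#' @export
labelStructures <- function(mask, scene = NULL, roi, channel = "puncta-A",
                            minSizePx = 4L, labels = NULL) {
  stopifnot(is(roi, "CellROI"))
  if (is.null(labels)) {
    labels <- labelConnected8(mask)
  } else {
    labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  }
  areas <- tabulate(labels[labels > 0L])
  drop <- which(areas < minSizePx)
  if (length(drop)) labels[labels %in% drop] <- 0L
  # relabel consecutively after the size filter
  present <- sort(unique(labels[labels > 0L]))
  if (length(present)) {
    labels[labels > 0L] <- match(labels[labels > 0L], present)
  }
  intensity <- if (is.null(scene)) {
    matrix(NA_real_, nrow(labels), ncol(labels))
  } else {
    getChannel(scene, channel)
  }
  px <- if (is.null(scene)) 1 else scene@pixelSize
  new("StructureSet", cellId = roi@cellId, channel = channel,
      labelMap = labels,
      stats = structureStats(labels, intensity, px),
      minSizePx = as.integer(minSizePx))
}

#' Split touching structures by watershed on the distance transform
#'
#' Marker-based watershed on the Euclidean distance transform of the mask,
#' with the distance map smoothed by a Gaussian (sigma = 1 px) and shallow
#' maxima merged by a tolerance so that small ridges do not over-segment.
#' The union of the output labels equals the input foreground.
#'
#' @param mask binary matrix.
#' @param smoothSigma numeric(1), Gaussian smoothing of the distance map in
#'   px (default 1).
#' @param tolerance numeric(1), minimum depth separating two maxima for
#'   them to seed distinct objects (px units of the distance map;
#'   default 1).
#' @return integer label matrix (0 background).
#' @export
splitTouching <- function(mask, smoothSigma = 1, tolerance = 1) {
  mask <- mask != 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(mask * 1)
  if (smoothSigma > 0) {
    dm <- EBImage::gblur(dm, sigma = smoothSigma)
    dm[!mask] <- 0
  }
  w <- EBImage::watershed(dm, tolerance = tolerance)
  matrix(as.integer(EBImage::imageData(w)), nrow(mask), ncol(mask))
}

#' Quality-control filter for cell ROIs
#'
#' Keeps cells whose nucleus is non-empty and judged in the focal plane
#' (both perinuclear and peripheral regions must be assessable). Exclusions
#' are reported via `message()`.
#'
#' @param rois list of [CellROI-class].
#' @return the kept subset, in input order.
#' @export
qcCells <- function(rois) {
  keep <- vapply(rois, function(r) {
    ok <- r@nucleusInPlane && any(r@nucleusMask)
    if (!ok) {
      message("cell ", r@cellId, " excluded: ",
              if (!any(r@nucleusMask)) "empty nucleus mask"
              else "nucleus not in focal plane")
    }
    ok
  }, logical(1))
  rois[keep]
}
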