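#' Per-structure size statistics and area fraction for one cell
#'
#' Converts structure areas to square micrometres and summarises them
#' (mean, median, count), together with the area fraction of the cell mask
#' covered by the structures — the two per-cell size readouts used for
#' vesicle-size and signal-coverage comparisons.
#'
#' @param structures a [StructureSet-class] (post-watershed labels when
#'   touching vesicles were split, raw components otherwise).
#' @param roi the owning [CellROI-class].
#' @param pixelSizeUm micrometres per pixel.
#' @return list with `perStructure` (data.frame label, area_px, area_um2),
#'   `meanAreaUm2`, `medianAreaUm2`, `count`, `areaFraction`.
#' @export
sizeStats <- function(structures, roi, pixelSizeUm) {
  stopifnot(is(structures, "StructureSet"), is(roi, "CellROI"))
  st <- structures@stats
  areasUm2 <- st$area_px * pixelSizeUm^2
  cellPx <- sum(roi@cellMask)
  list(cellId = structures@cellId,
       channel = structures@channel,
       perStructure = data.frame(label = st$label, area_px = st$area_px,
                                 area_um2 = areasUm2),
       meanAreaUm2 = if (nrow(st)) mean(areasUm2) else NA_real_,
       medianAreaUm2 = if (nrow(st)) median(areasUm2) else NA_real_,
       count = nrow(st),
       areaFraction = sum(st$area_px) / cellPx)
}

#' Mean-intensity comparison between a clone cell and a neighbour control
#'
#' Mean gray value of one channel over each full cell mask, and their
#' clone / control ratio — the readout for markers whose abundance changes
#' in the genetically modified cell relative to its unmodified neighbour.
#'
#' @param scene a [TissueScene-class].
#' @param cloneRoi,controlRoi [CellROI-class] for the clone cell and its
#'   neighbouring control.
#' @param role channel role to measure.
#' @param subtractBackground numeric(1), constant subtracted from both
#'   means before the ratio (default 0).
#' @return list with `cloneMean`, `controlMean`, `ratio`,
#'   `cloneId`, `controlId`.
#' @export
neighborIntensityRatio <- function(scene, cloneRoi, controlRoi, role,
                                   subtractBackground = 0) {
  stopifnot(is(scene, "TissueScene"), is(cloneRoi, "CellROI"),
            is(controlRoi, "CellROI"))
  ch <- getChannel(scene, role)
  if (!any(cloneRoi@cellMask) || !any(controlRoi@cellMask)) {
    stop("both cell masks must be non-empty")
  }
  mClone <- mean(ch[cloneRoi@cellMask]) - subtractBackground
  mControl <- mean(ch[controlRoi@cellMask]) - subtractBackground
  list(cloneId = cloneRoi@cellId, controlId = controlRoi@cellId,
       cloneMean = mClone, controlMean = mControl,
       ratio = mClone / mControl)
}
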