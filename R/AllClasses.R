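#' SceneSpec: parameters of a synthetic mosaic-tissue scene
#'
#' Describes the geometry and noise model of a synthetic field of polygonal,
#' space-filling cells (a fat-body-like mosaic): field size, pixel size, cell
#' count, fraction of clone-positive (genetically marked) cells, relative
#' nucleus size, and an additive-Gaussian (optionally Poisson-compounded)
#' noise model. Identical specs with identical seeds produce bit-identical
#' scenes.
#'
#' @slot fieldSize integer(2), image height and width in pixels.
#' @slot pixelSize numeric(1), physical pixel size in micrometres.
#' @slot nCells integer(1), number of cells tiling the field.
#' @slot cloneFraction numeric(1) in [0, 1], fraction of clone-positive cells.
#' @slot nucleusRatio numeric(1) in (0, 1), nucleus-to-cell radius ratio.
#' @slot seed integer(1), random seed; the determinism contract key.
#' @slot background numeric(1), constant background intensity added to every
#'   channel before noise.
#' @slot noiseSd numeric(1), standard deviation of additive Gaussian noise.
#' @slot poissonNoise logical(1), whether to apply a signal-dependent Poisson
#'   stage before the additive noise.
#' @slot tissueEdge logical(1), whether cells touching the field margin are
#'   flagged as facing a free tissue edge (the hemolymph-facing side).
#' @slot cloneBoost numeric(1), multiplicative intensity enhancement applied
#'   to puncta channels inside clone-positive cells (1 = none); emulates
#'   signal-intensity differences between marked and neighbouring cells.
#' @seealso [sceneSpec()], [generateScene()]
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    fieldSize = "integer",
    pixelSize = "numeric",
    nCells = "integer",
    cloneFraction = "numeric",
    nucleusRatio = "numeric",
    seed = "integer",
    background = "numeric",
    noiseSd = "numeric",
    poissonNoise = "logical",
    tissueEdge = "logical",
    cloneBoost = "numeric"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@fieldSize) != 2L || any(object@fieldSize < 16L))
    msg <- c(msg, "fieldSize must be two integers >= 16")
  if (object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (object@nCells < 1L)
    msg <- c(msg, "nCells must be >= 1")
  if (object@cloneFraction < 0 || object@cloneFraction > 1)
    msg <- c(msg, "cloneFraction must lie in [0, 1]")
  if (object@nucleusRatio <= 0 || object@nucleusRatio >= 1)
    msg <- c(msg, "nucleusRatio must lie strictly inside (0, 1)")
  if (object@noiseSd < 0 || object@background < 0)
    msg <- c(msg, "background and noiseSd must be >= 0")
  if (object@cloneBoost <= 0)
    msg <- c(msg, "cloneBoost must be > 0")
  if (length(msg)) msg else TRUE
})

#' PunctaSpec: placement and rendering rules for one puncta channel
#'
#' Spots are isotropic 2D Gaussians truncated at 3 sigma with
#' sigma = radius / 2, placed per cell according to a spatial mode:
#' \describe{
#'   \item{perinuclear / peripheral}{each spot is drawn uniformly inside the
#'     cell's perinuclear equal-area domain with probability `f`, otherwise
#'     inside the peripheral domain; the domains are the ones
#'     [equalAreaPartition()] computes, so generator truth and scorer
#'     definition coincide.}
#'   \item{uniform}{spots uniform over the whole cytoplasm.}
#'   \item{ectopic_focus}{spots clustered (Gaussian spread) around a focus
#'     displaced from the nucleus, emulating organelle aggregation at a
#'     relocated microtubule-organizing centre.}
#' }
#'
#' @slot role character(1), channel role name (e.g. "puncta-A").
#' @slot mode character(1), one of "perinuclear", "peripheral", "uniform",
#'   "ectopic_focus".
#' @slot f numeric(1) in [0, 1], probability that a spot is placed in the
#'   perinuclear domain (the ground-truth placement bias).
#' @slot nSpots integer(1) >= 0, spots per cell.
#' @slot radiusMeanUm,radiusSdUm numeric(1), spot radius distribution in um.
#' @slot peakIntensity numeric(1), peak amplitude of a rendered spot.
#' @slot focusOffsetUm numeric(1), distance of the ectopic focus centre from
#'   the nucleus boundary (um); used by mode "ectopic_focus".
#' @slot focusSpreadUm numeric(1), Gaussian spread of spots around the
#'   ectopic focus (um).
#' @slot edgeBias logical(1), for mode "peripheral" in edge-touching cells:
#'   weight placement toward the free tissue margin (off by default).
#' @seealso [punctaSpec()]
#' @exportClass PunctaSpec
setClass("PunctaSpec",
  representation(
    role = "character",
    mode = "character",
    f = "numeric",
    nSpots = "integer",
    radiusMeanUm = "numeric",
    radiusSdUm = "numeric",
    peakIntensity = "numeric",
    focusOffsetUm = "numeric",
    focusSpreadUm = "numeric",
    edgeBias = "logical"
  )
)

setValidity("PunctaSpec", function(object) {
  msg <- character()
  if (!object@mode %in% c("perinuclear", "peripheral", "uniform",
                          "ectopic_focus"))
    msg <- c(msg, "mode must be perinuclear, peripheral, uniform or ectopic_focus")
  if (object@f < 0 || object@f > 1)
    msg <- c(msg, "f must lie in [0, 1]")
  if (object@nSpots < 0L)
    msg <- c(msg, "nSpots must be >= 0")
  if (object@radiusMeanUm <= 0 || object@radiusSdUm < 0)
    msg <- c(msg, "spot radii must be > 0")
  if (object@peakIntensity <= 0)
    msg <- c(msg, "peakIntensity must be > 0")
  if (length(msg)) msg else TRUE
})

#' TissueScene: a multi-channel 2D image with channel roles
#'
#' The imaging substrate of the pipeline: a named list of equally shaped 2D
#' intensity matrices (one per fluorescence channel), the physical pixel
#' size, and provenance metadata. Pixels are addressed `[row, col]`
#' (row-major raster order for deterministic tie-breaking); a pixel belongs
#' to a mask iff its value is nonzero.
#'
#' @slot channels named list of numeric matrices, one per channel role.
#' @slot pixelSize numeric(1), micrometres per pixel.
#' @slot metadata list, provenance (generator spec hash or source paths).
#' @seealso [getChannel()], [loadScene()], [generateScene()]
#' @exportClass TissueScene
setClass("TissueScene",
  representation(
    channels = "list",
    pixelSize = "numeric",
    metadata = "list"
  )
)

setValidity("TissueScene", function(object) {
  msg <- character()
  if (length(object@channels) < 1L)
    msg <- c(msg, "scene must hold at least one channel")
  if (is.null(names(object@channels)) || any(!nzchar(names(object@channels))))
    msg <- c(msg, "every channel must be named by its role")
  dims <- lapply(object@channels, dim)
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all channels must share one shape")
  if (object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' CellROI: one cell's masks and per-cell flags
#'
#' @slot cellId integer(1), cell identifier.
#' @slot cellMask logical matrix, the cell region (full field size).
#' @slot nucleusMask logical matrix, the nucleus; must lie inside the cell
#'   mask, and the cytoplasm (cell minus nucleus) must be non-empty.
#' @slot cloneStatus logical(1), whether the cell is clone-positive.
#' @slot tissueEdge logical(1), whether the cell touches the field margin
#'   (free tissue edge).
#' @slot nucleusInPlane logical(1), whether the nucleus is judged to be in
#'   the focal plane; cells failing this are excluded by [qcCells()].
#' @seealso [qcCells()], [equalAreaPartition()]
#' @exportClass CellROI
setClass("CellROI",
  representation(
    cellId = "integer",
    cellMask = "matrix",
    nucleusMask = "matrix",
    cloneStatus = "logical",
    tissueEdge = "logical",
    nucleusInPlane = "logical"
  )
)

setValidity("CellROI", function(object) {
  msg <- character()
  if (!identical(dim(object@cellMask), dim(object@nucleusMask)))
    msg <- c(msg, "cell and nucleus masks must share one shape")
  if (!any(object@cellMask))
    msg <- c(msg, "cell mask must be non-empty")
  if (any(object@nucleusMask & !object@cellMask))
    msg <- c(msg, "nucleus mask must lie inside the cell mask")
  if (!any(object@cellMask & !object@nucleusMask))
    msg <- c(msg, "cytoplasm (cell minus nucleus) must be non-empty")
  if (length(msg)) msg else TRUE
})

#' StructureSet: labeled above-threshold structures within one cell
#'
#' Connected components (8-connectivity) of a thresholded channel within one
#' cell mask, with per-structure statistics.
#'
#' @slot cellId integer(1), owning cell.
#' @slot channel character(1), channel role the structures came from.
#' @slot labelMap integer matrix, 0 = background, k = structure k.
#' @slot stats data.frame with one row per structure: `label`, `area_px`,
#'   `area_um2`, `centroid_row`, `centroid_col`, `mean_intensity`,
#'   `bbox_rmin`, `bbox_rmax`, `bbox_cmin`, `bbox_cmax`.
#' @slot minSizePx integer(1), minimum structure size applied.
#' @seealso [labelStructures()], [splitTouching()]
#' @exportClass StructureSet
setClass("StructureSet",
  representation(
    cellId = "integer",
    channel = "character",
    labelMap = "matrix",
    stats = "data.frame",
    minSizePx = "integer"
  )
)

setValidity("StructureSet", function(object) {
  msg <- character()
  labs <- object@labelMap[object@labelMap > 0L]
  present <- sort(unique(labs))
  if (!identical(as.integer(sort(object@stats$label)), as.integer(present)))
    msg <- c(msg, "stats rows must match the labels present in labelMap")
  if (nrow(object@stats) && any(object@stats$area_px < object@minSizePx))
    msg <- c(msg, "every structure must reach the minimum size")
  if (length(msg)) msg else TRUE
})

#' DomainPartition: equal-area perinuclear/peripheral split of a cytoplasm
#'
#' The two domains partition the cytoplasm exactly; their pixel areas differ
#' by at most 1 px, and every perinuclear pixel is at most as far from the
#' nucleus as every peripheral pixel (up to ties at the split distance,
#' resolved in raster order).
#'
#' @slot cellId integer(1).
#' @slot perinuclear,peripheral logical matrices, the two domains.
#' @slot splitDistance numeric(1), the half-area distance d* in pixels.
#' @slot areaDifference integer(1), |area(peri) - area(periph)| in px
#'   (0 or 1 by construction).
#' @seealso [equalAreaPartition()], [distributionIndex()]
#' @exportClass DomainPartition
setClass("DomainPartition",
  representation(
    cellId = "integer",
    perinuclear = "matrix",
    peripheral = "matrix",
    splitDistance = "numeric",
    areaDifference = "integer"
  )
)

setValidity("DomainPartition", function(object) {
  msg <- character()
  if (any(object@perinuclear & object@peripheral))
    msg <- c(msg, "domains must be disjoint")
  if (abs(sum(object@perinuclear) - sum(object@peripheral)) > 1L)
    msg <- c(msg, "domain areas must differ by at most 1 px")
  if (length(msg)) msg else TRUE
})

#' DistributionResult: the signed perinuclear distribution index of one cell
#'
#' Holds the three signal areas and the index
#' D = (A_peri - A_periph) / A_total, with D in [-1, 1]: +1 perfectly
#' perinuclear, 0 evenly dispersed, -1 perfectly peripheral. When no signal
#' is present (A_total = 0) the result is flagged undefined rather than
#' raising an error.
#'
#' @slot cellId integer(1).
#' @slot channel character(1).
#' @slot APeri,APeriph,ATotal numeric(1), signal areas (px) in the
#'   perinuclear domain, the peripheral domain, and the whole cytoplasm.
#' @slot D numeric(1), the signed index (NA when undefined).
#' @slot defined logical(1), FALSE iff A_total = 0.
#' @seealso [distributionIndex()]
#' @exportClass DistributionResult
setClass("DistributionResult",
  representation(
    cellId = "integer",
    channel = "character",
    APeri = "numeric",
    APeriph = "numeric",
    ATotal = "numeric",
    D = "numeric",
    defined = "logical"
  )
)

setValidity("DistributionResult", function(object) {
  msg <- character()
  if (object@defined) {
    if (abs(object@APeri + object@APeriph - object@ATotal) > 1e-9)
      msg <- c(msg, "A_peri + A_periph must equal A_total")
    if (is.na(object@D) || object@D < -1 || object@D > 1)
      msg <- c(msg, "D must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px @ %.3g um/px, %d cells (clone fraction %.2f), seed %d\n",
    object@fieldSize[1], object@fieldSize[2], object@pixelSize,
    object@nCells, object@cloneFraction, object@seed))
  cat(sprintf("  noise: background %.3g + N(0, %.3g)%s; nucleus ratio %.2f\n",
              object@background, object@noiseSd,
              if (object@poissonNoise) " after Poisson stage" else "",
              object@nucleusRatio))
})

setMethod("show", "PunctaSpec", function(object) {
  cat(sprintf(
    "PunctaSpec '%s': mode %s (f = %.2f), %d spots/cell, radius %.2g +/- %.2g um\n",
    object@role, object@mode, object@f, object@nSpots,
    object@radiusMeanUm, object@radiusSdUm))
})

setMethod("show", "TissueScene", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("TissueScene: %d x %d px @ %.3g um/px, channels: %s\n",
              d[1], d[2], object@pixelSize,
              paste(names(object@channels), collapse = ", ")))
})

setMethod("show", "CellROI", function(object) {
  cat(sprintf(
    "CellROI %d: cell %d px, nucleus %d px, clone=%s, edge=%s, inPlane=%s\n",
    object@cellId, sum(object@cellMask), sum(object@nucleusMask),
    object@cloneStatus, object@tissueEdge, object@nucleusInPlane))
})

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet: cell %d, channel '%s', %d structures\n",
              object@cellId, object@channel, nrow(object@stats)))
})

setMethod("show", "DomainPartition", function(object) {
  cat(sprintf(
    "DomainPartition: cell %d, d* = %.2f px, areas %d | %d px (diff %d)\n",
    object@cellId, object@splitDistance, sum(object@perinuclear),
    sum(object@peripheral), object@areaDifference))
})

setMethod("show", "DistributionResult", function(object) {
  if (object@defined) {
    cat(sprintf(
      "DistributionResult: cell %d '%s', D = %.4f (A_peri %d, A_periph %d, A_total %d)\n",
      object@cellId, object@channel, object@D, object@APeri, object@APeriph,
      object@ATotal))
  } else {
    cat(sprintf("DistributionResult: cell %d '%s', undefined (no signal)\n",
                object@cellId, object@channel))
  }
})
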