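#' Construct a SceneSpec
#'
#' Defaults describe a modest mosaic field: 512 x 512 px at 0.2 um/px,
#' 16 polygonal cells of which half are clone-positive, a nucleus about a
#' third of the cell radius, constant background 10 with Gaussian read noise
#' (sd 2). See [SceneSpec-class] for the meaning of every field.
#'
#' @param fieldSize integer(2), height and width in pixels.
#' @param pixelSize numeric(1), micrometres per pixel.
#' @param nCells integer(1), cells tiling the field.
#' @param cloneFraction numeric(1) in [0, 1].
#' @param nucleusRatio numeric(1) in (0, 1), nucleus-to-cell radius ratio.
#' @param seed integer(1), random seed.
#' @param background,noiseSd noise model (constant background plus additive
#'   Gaussian noise).
#' @param poissonNoise logical(1), apply a Poisson stage before the
#'   Gaussian noise.
#' @param tissueEdge logical(1), flag margin-touching cells as edge cells.
#' @param cloneBoost numeric(1), puncta intensity multiplier in clone cells.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(fieldSize = c(512L, 512L), pixelSize = 0.2,
                      nCells = 16L, cloneFraction = 0.5,
                      nucleusRatio = 0.35, seed = 1L,
                      background = 10, noiseSd = 2,
                      poissonNoise = FALSE, tissueEdge = TRUE,
                      cloneBoost = 1) {
  new("SceneSpec",
      fieldSize = as.integer(fieldSize), pixelSize = pixelSize,
      nCells = as.integer(nCells), cloneFraction = cloneFraction,
      nucleusRatio = nucleusRatio, seed = as.integer(seed),
      background = background, noiseSd = noiseSd,
      poissonNoise = poissonNoise, tissueEdge = tissueEdge,
      cloneBoost = cloneBoost)
}

#' Construct a PunctaSpec
#'
#' When `f` is not given it defaults to 1 for mode "perinuclear", 0 for
#' "peripheral" and 0.5 otherwise; `f` is the probability that a spot is
#' drawn inside the perinuclear equal-area domain, i.e. the ground-truth
#' placement bias (the expected distribution index of a cohort is 2f - 1).
#'
#' @param role character(1), channel role, e.g. "puncta-A".
#' @param mode one of "perinuclear", "peripheral", "uniform",
#'   "ectopic_focus".
#' @param f numeric(1) in [0, 1], perinuclear placement probability.
#' @param nSpots integer(1), spots per cell.
#' @param radiusMeanUm,radiusSdUm spot radius distribution (um).
#' @param peakIntensity peak amplitude of a rendered spot.
#' @param focusOffsetUm,focusSpreadUm ectopic-focus geometry (um).
#' @param edgeBias logical(1), weight peripheral placement toward the free
#'   tissue margin in edge-touching cells.
#' @return a [PunctaSpec-class].
#' @export
punctaSpec <- function(role = "puncta-A",
                       mode = c("perinuclear", "peripheral", "uniform",
                                "ectopic_focus"),
                       f = NULL, nSpots = 50L,
                       radiusMeanUm = 0.3, radiusSdUm = 0.05,
                       peakIntensity = 200,
                       focusOffsetUm = 8, focusSpreadUm = 1.5,
                       edgeBias = FALSE) {
  mode <- match.arg(mode)
  if (is.null(f)) {
    f <- switch(mode, perinuclear = 1, peripheral = 0, 0.5)
  }
  new("PunctaSpec",
      role = role, mode = mode, f = f, nSpots = as.integer(nSpots),
      radiusMeanUm = radiusMeanUm, radiusSdUm = radiusSdUm,
      peakIntensity = peakIntensity, focusOffsetUm = focusOffsetUm,
      focusSpreadUm = focusSpreadUm, edgeBias = edgeBias)
}

# Add one truncated (3 sigma) isotropic Gaussian spot into a channel matrix.
renderSpot <- function(ch, rowc, colc, sigmaPx, peak) {
  ext <- ceiling(3 * sigmaPx)
  rows <- max(1L, floor(rowc - ext)):min(nrow(ch), ceiling(rowc + ext))
  cols <- max(1L, floor(colc - ext)):min(ncol(ch), ceiling(colc + ext))
  if (length(rows) == 0L || length(cols) == 0L) return(ch)
  dr2 <- outer((rows - rowc)^2, (cols - colc)^2, "+")
  g <- peak * exp(-dr2 / (2 * sigmaPx^2))
  g[dr2 > (3 * sigmaPx)^2] <- 0
  ch[rows, cols] <- ch[rows, cols] + g
  ch
}

# Voronoi tessellation of seed points over the field; returns a label matrix
# (1..n) before boundary erosion. Ties go to the lowest seed id.
voronoiLabels <- function(fieldSize, seeds) {
  nr <- fieldSize[1]; nc <- fieldSize[2]
  rw <- rep(seq_len(nr), times = nc)
  cl <- rep(seq_len(nc), each = nr)
  best <- rep.int(Inf, nr * nc)
  lab <- rep.int(0L, nr * nc)
  for (i in seq_len(nrow(seeds))) {
    d <- (rw - seeds[i, 1])^2 + (cl - seeds[i, 2])^2
    upd <- d < best
    best[upd] <- d[upd]
    lab[upd] <- i
  }
  matrix(lab, nr, nc)
}

# Boundary pixels of a label map: any pixel with a 4-neighbour carrying a
# different label; eroding these creates a background seam between cells.
boundaryPixels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  b <- matrix(FALSE, nr, nc)
  diffDown <- lab[-nr, ] != lab[-1, ]
  b[-nr, ][diffDown] <- TRUE
  b[-1, ][diffDown] <- TRUE
  diffRight <- lab[, -nc] != lab[, -1]
  b[, -nc][diffRight] <- TRUE
  b[, -1][diffRight] <- TRUE
  b
}

# Largest inscribed-disk centre and radius of a mask, with the field edge
# treated as boundary (so nuclei stay strictly inside cells).
inscribedDisk <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1
  dm <- EBImage::distmap(padded)
  dm <- matrix(dm, nr + 2L, nc + 2L)[2:(nr + 1L), 2:(nc + 1L)]
  k <- which.max(dm)
  list(center = c(((k - 1L) %% nr) + 1L, ((k - 1L) %/% nr) + 1L),
       radius = dm[k])
}

# Sample one spot centre: a cytoplasm pixel plus sub-pixel jitter that keeps
# the rounded centre on the sampled pixel.
sampleCenter <- function(pixels, nr, weights = NULL) {
  k <- if (is.null(weights)) {
    pixels[sample.int(length(pixels), 1L)]
  } else {
    pixels[sample.int(length(pixels), 1L, prob = weights)]
  }
  c(((k - 1L) %% nr) + 1L + runif(1, -0.49, 0.49),
    ((k - 1L) %/% nr) + 1L + runif(1, -0.49, 0.49))
}

# Apply the SceneSpec noise model to one channel and quantise to integers.
applyNoise <- function(ch, spec) {
  if (spec@poissonNoise) {
    ch <- matrix(rpois(length(ch), lambda = pmax(ch, 0)),
                 nrow(ch), ncol(ch))
  }
  ch <- ch + spec@background
  if (spec@noiseSd > 0) {
    ch <- ch + matrix(rnorm(length(ch), sd = spec@noiseSd),
                      nrow(ch), ncol(ch))
  }
  matrix(pmin(pmax(round(ch), 0), 65535), nrow(ch), ncol(ch))
}

# Place and render the spots of one PunctaSpec in one cell. Returns the
# updated channel and the ground-truth rows.
placeCellSpots <- function(ch, pspec, roi, part, spec, intensityScale = 1) {
  nSpots <- pspec@nSpots
  if (nSpots == 0L) return(list(channel = ch, truth = NULL))
  nr <- nrow(ch)
  cyto <- which(cytoplasmMask(roi))
  periIdx <- which(part@perinuclear)
  periphIdx <- which(part@peripheral)

  # reject impossible spot sizes: a spot may not be larger than its cell
  cellRadiusPx <- sqrt(sum(roi@cellMask) / pi)
  if (pspec@radiusMeanUm / spec@pixelSize > cellRadiusPx) {
    stop("spot radius (", pspec@radiusMeanUm, " um = ",
         round(pspec@radiusMeanUm / spec@pixelSize, 1),
         " px) is larger than cell ", roi@cellId,
         " (equivalent radius ", round(cellRadiusPx, 1), " px)")
  }

  # ectopic focus geometry: displace the focus from the nucleus boundary
  # toward the cytoplasmic point farthest from the nucleus
  if (pspec@mode == "ectopic_focus") {
    bb <- maskBBox(roi@cellMask, pad = 1L)
    d2 <- matrix(NA_real_, nr, ncol(ch))
    d2[bb$rows, bb$cols] <-
      squaredDistanceTransform(roi@nucleusMask[bb$rows, bb$cols,
                                               drop = FALSE])
    far <- cyto[which.max(d2[cyto])]
    farRC <- c(((far - 1L) %% nr) + 1L, ((far - 1L) %/% nr) + 1L)
    nuc <- which(roi@nucleusMask)
    nucRC <- c(mean(((nuc - 1L) %% nr) + 1L),
               mean(((nuc - 1L) %/% nr) + 1L))
    u <- farRC - nucRC
    u <- u / sqrt(sum(u^2))
    nucEqR <- sqrt(length(nuc) / pi)
    focus <- nucRC + u * (nucEqR + pspec@focusOffsetUm / spec@pixelSize)
    # snap the focus onto the cytoplasm
    rows <- ((cyto - 1L) %% nr) + 1L
    cols <- ((cyto - 1L) %/% nr) + 1L
    snap <- which.min((rows - focus[1])^2 + (cols - focus[2])^2)
    focus <- c(rows[snap], cols[snap])
    spreadPx <- pspec@focusSpreadUm / spec@pixelSize
    cytoSet <- logical(nr * ncol(ch))
    cytoSet[cyto] <- TRUE
  }

  # optional weighting of peripheral placement toward the field margin
  periphWeights <- NULL
  if (pspec@edgeBias && roi@tissueEdge && length(periphIdx)) {
    rows <- ((periphIdx - 1L) %% nr) + 1L
    cols <- ((periphIdx - 1L) %/% nr) + 1L
    margin <- pmin(rows - 1L, nr - rows, cols - 1L, ncol(ch) - cols)
    periphWeights <- 1 / (1 + margin)
  }

  truth <- vector("list", nSpots)
  for (s in seq_len(nSpots)) {
    radiusUm <- max(pspec@radiusMeanUm / 4,
                    rnorm(1, pspec@radiusMeanUm, pspec@radiusSdUm))
    sigmaPx <- max(radiusUm / spec@pixelSize / 2, 0.3)  # sigma = radius/2

    if (pspec@mode %in% c("perinuclear", "peripheral")) {
      inPeri <- runif(1) < pspec@f
      pool <- if (inPeri) periIdx else periphIdx
      w <- if (!inPeri) periphWeights else NULL
      if (length(pool) == 0L) pool <- cyto
      center <- sampleCenter(pool, nr, w)
    } else if (pspec@mode == "uniform") {
      center <- sampleCenter(cyto, nr)
    } else {  # ectopic_focus
      center <- NULL
      for (try in seq_len(200L)) {
        cand <- focus + rnorm(2, sd = spreadPx)
        k <- round(cand[1]) + (round(cand[2]) - 1L) * nr
        if (round(cand[1]) >= 1 && round(cand[1]) <= nr &&
            round(cand[2]) >= 1 && round(cand[2]) <= ncol(ch) &&
            cytoSet[k]) {
          center <- cand
          break
        }
      }
      if (is.null(center)) {
        center <- c(focus[1] + runif(1, -0.49, 0.49),
                    focus[2] + runif(1, -0.49, 0.49))
      }
    }

    ch <- renderSpot(ch, center[1], center[2], sigmaPx,
                     pspec@peakIntensity * intensityScale)
    centerPix <- round(center[1]) + (round(center[2]) - 1L) * nrow(ch)
    truth[[s]] <- data.frame(
      cell_id = roi@cellId, channel = pspec@role,
      row = center[1], col = center[2],
      radius_um = radiusUm, sigma_px = sigmaPx,
      domain = if (part@perinuclear[centerPix]) "perinuclear"
               else "peripheral",
      f = pspec@f, mode = pspec@mode, pair_id = NA_integer_)
  }
  list(channel = ch, truth = do.call(rbind, truth))
}

#' Generate a synthetic mosaic-tissue scene with ground truth
#'
#' Builds a field of polygonal, space-filling cells (Voronoi tessellation of
#' well-spaced random seeds, boundaries eroded by 1 px), places one round
#' nucleus per cell strictly inside the cell, marks a fraction of cells as
#' clone-positive, renders each requested puncta channel as truncated 2D
#' Gaussian spots placed per the [PunctaSpec-class] spatial mode, and
#' finally applies the noise model. Perinuclear/peripheral placement uses
#' the same equal-area domains that [equalAreaPartition()] computes, so
#' ground truth and scorer agree by construction. The run is bit-exactly
#' reproducible from the spec and its seed.
#'
#' @param spec a [SceneSpec-class].
#' @param puncta list of [PunctaSpec-class] (one rendered channel each).
#' @return list with `scene` (a [TissueScene-class] holding channels
#'   "clone", "nucleus" and one per puncta role), `rois` (list of
#'   [CellROI-class]), and `truth` (data.frame, one row per rendered spot:
#'   cell_id, channel, row, col, radius_um, sigma_px, domain, f, mode,
#'   pair_id).
#' @examples
#' sim <- generateScene(sceneSpec(fieldSize = c(192L, 192L), nCells = 4L,
#'                                seed = 7L),
#'                      list(punctaSpec("puncta-A", "perinuclear",
#'                                      nSpots = 20L)))
#' sim$scene
#' @export
generateScene <- function(spec, puncta = list()) {
  stopifnot(is(spec, "SceneSpec"))
  if (is(puncta, "PunctaSpec")) puncta <- list(puncta)
  set.seed(spec@seed)
  nr <- spec@fieldSize[1]; nc <- spec@fieldSize[2]

  # well-spaced seeds: jittered grid covering the field
  n <- spec@nCells
  gr <- max(1L, round(sqrt(n * nr / nc)))
  gc <- ceiling(n / gr)
  while (gr * gc < n) gc <- gc + 1L
  cellH <- nr / gr; cellW <- nc / gc
  slots <- sample(gr * gc, n)
  seeds <- cbind(
    ((slots - 1L) %% gr) * cellH + runif(n, 0.25, 0.75) * cellH,
    ((slots - 1L) %/% gr) * cellW + runif(n, 0.25, 0.75) * cellW)
  lab <- voronoiLabels(c(nr, nc), seeds)
  lab[boundaryPixels(lab)] <- 0L

  cloneIds <- sort(sample(n, round(spec@cloneFraction * n)))
  rois <- vector("list", n)
  for (i in seq_len(n)) {
    cmask <- lab == i
    if (!any(cmask)) stop("degenerate tessellation: cell ", i, " is empty")
    disk <- inscribedDisk(cmask)
    nucR <- min(spec@nucleusRatio * sqrt(sum(cmask) / pi), disk$radius - 2)
    if (nucR < 2) {
      stop("cell ", i, " too small to hold a nucleus; reduce nCells or ",
           "nucleusRatio")
    }
    nmask <- diskMask(nr, nc, disk$center, nucR) & cmask
    touches <- any(cmask[1, ]) || any(cmask[nr, ]) ||
      any(cmask[, 1]) || any(cmask[, nc])
    rois[[i]] <- new("CellROI", cellId = i, cellMask = cmask,
                     nucleusMask = nmask,
                     cloneStatus = i %in% cloneIds,
                     tissueEdge = spec@tissueEdge && touches,
                     nucleusInPlane = TRUE)
  }

  channels <- list(
    clone = matrix(0, nr, nc),
    nucleus = matrix(0, nr, nc))
  for (roi in rois) {
    if (roi@cloneStatus) channels$clone[roi@cellMask] <- 120
    channels$nucleus[roi@nucleusMask] <- 180
  }

  truth <- NULL
  parts <- lapply(rois, equalAreaPartition)
  for (pspec in puncta) {
    ch <- matrix(0, nr, nc)
    for (i in seq_len(n)) {
      boost <- if (rois[[i]]@cloneStatus) spec@cloneBoost else 1
      placed <- placeCellSpots(ch, pspec, rois[[i]], parts[[i]], spec,
                               intensityScale = boost)
      ch <- placed$channel
      truth <- rbind(truth, placed$truth)
    }
    channels[[pspec@role]] <- ch
  }

  channels <- lapply(channels, applyNoise, spec = spec)
  scene <- new("TissueScene", channels = channels,
               pixelSize = spec@pixelSize,
               metadata = list(generator = "generateScene",
                               seed = spec@seed, nCells = n))
  if (is.null(truth)) {
    truth <- data.frame(cell_id = integer(), channel = character(),
                        row = numeric(), col = numeric(),
                        radius_um = numeric(), sigma_px = numeric(),
                        domain = character(), f = numeric(),
                        mode = character(), pair_id = integer())
  }
  list(scene = scene, rois = rois, truth = truth)
}

#' Generate a synthetic single cultured cell with controlled colocalization
#'
#' Emulates a cultured-cell colocalization experiment: one round cell with a
#' nucleus, two puncta channels, and a controlled fraction of channel-A
#' spots co-centred with a channel-B spot. Non-paired spots of the two
#' channels are kept apart by a minimum separation so that true pairings are
#' unambiguous. Pairings are recorded in the ground truth through `pair_id`.
#'
#' @param spec a [SceneSpec-class] (nCells is ignored; one cell is built).
#' @param colocFraction numeric(1) in [0, 1], fraction of A spots that get a
#'   co-centred B partner; the realised count is
#'   `round(colocFraction * nSpots_A)`.
#' @param punctaA,punctaB [PunctaSpec-class] for the two channels. The B
#'   channel renders its paired spots plus `max(0, nSpots_B - paired)`
#'   independent ones.
#' @param minSeparationUm numeric(1), minimum distance between non-paired
#'   spot centres (default: sum of the two 3-sigma footprints).
#' @return list with `scene`, `roi` and `truth` as in [generateScene()];
#'   paired rows of the two channels share a `pair_id`.
#' @export
generateCulturedCell <- function(spec, colocFraction,
                                 punctaA = punctaSpec("puncta-A", "uniform"),
                                 punctaB = punctaSpec("puncta-B", "uniform"),
                                 minSeparationUm = NULL) {
  stopifnot(is(spec, "SceneSpec"))
  if (colocFraction < 0 || colocFraction > 1) {
    stop("colocFraction must lie in [0, 1]")
  }
  set.seed(spec@seed)
  nr <- spec@fieldSize[1]; nc <- spec@fieldSize[2]
  center <- c((nr + 1) / 2, (nc + 1) / 2)
  cellR <- 0.44 * min(nr, nc)
  cmask <- diskMask(nr, nc, center, cellR)
  nmask <- diskMask(nr, nc, center, spec@nucleusRatio * cellR)
  roi <- new("CellROI", cellId = 1L, cellMask = cmask, nucleusMask = nmask,
             cloneStatus = TRUE, tissueEdge = FALSE, nucleusInPlane = TRUE)
  cyto <- which(cytoplasmMask(roi))

  sigmaA <- max(punctaA@radiusMeanUm / spec@pixelSize / 2, 0.3)
  sigmaB <- max(punctaB@radiusMeanUm / spec@pixelSize / 2, 0.3)
  if (is.null(minSeparationUm)) {
    minSeparationUm <- (3 * sigmaA + 3 * sigmaB + 2) * spec@pixelSize
  }
  minSepPx <- minSeparationUm / spec@pixelSize
  if (punctaA@radiusMeanUm / spec@pixelSize > cellR) {
    stop("spot radius is larger than the cell")
  }

  placed <- matrix(numeric(0), ncol = 2)
  drawSeparated <- function() {
    for (try in seq_len(2000L)) {
      cand <- sampleCenter(cyto, nr)
      if (nrow(placed) == 0L ||
          min((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2) >=
            minSepPx^2) {
        placed <<- rbind(placed, cand)
        return(cand)
      }
    }
    stop("could not place ", punctaA@nSpots + punctaB@nSpots,
         " spots at the requested separation; reduce spot count or ",
         "separation")
  }

  chA <- matrix(0, nr, nc)
  chB <- matrix(0, nr, nc)
  nA <- punctaA@nSpots
  nPaired <- as.integer(round(colocFraction * nA))
  pairedA <- if (nA > 0L) sort(sample(nA, nPaired)) else integer()
  truth <- vector("list", 0)

  centersA <- vector("list", nA)
  for (s in seq_len(nA)) {
    cen <- drawSeparated()
    centersA[[s]] <- cen
    rA <- max(punctaA@radiusMeanUm / 4,
              rnorm(1, punctaA@radiusMeanUm, punctaA@radiusSdUm))
    sA <- max(rA / spec@pixelSize / 2, 0.3)
    chA <- renderSpot(chA, cen[1], cen[2], sA, punctaA@peakIntensity)
    truth[[length(truth) + 1L]] <- data.frame(
      cell_id = 1L, channel = punctaA@role, row = cen[1], col = cen[2],
      radius_um = rA, sigma_px = sA, domain = NA_character_,
      f = punctaA@f, mode = "uniform",
      pair_id = if (s %in% pairedA) match(s, pairedA) else NA_integer_)
  }
  # paired B spots: co-centred with their A partner
  for (p in seq_along(pairedA)) {
    cen <- centersA[[pairedA[p]]]
    rB <- max(punctaB@radiusMeanUm / 4,
              rnorm(1, punctaB@radiusMeanUm, punctaB@radiusSdUm))
    sB <- max(rB / spec@pixelSize / 2, 0.3)
    chB <- renderSpot(chB, cen[1], cen[2], sB, punctaB@peakIntensity)
    truth[[length(truth) + 1L]] <- data.frame(
      cell_id = 1L, channel = punctaB@role, row = cen[1], col = cen[2],
      radius_um = rB, sigma_px = sB, domain = NA_character_,
      f = punctaB@f, mode = "uniform", pair_id = p)
  }
  # independent B spots
  nBfree <- max(0L, punctaB@nSpots - nPaired)
  for (s in seq_len(nBfree)) {
    cen <- drawSeparated()
    rB <- max(punctaB@radiusMeanUm / 4,
              rnorm(1, punctaB@radiusMeanUm, punctaB@radiusSdUm))
    sB <- max(rB / spec@pixelSize / 2, 0.3)
    chB <- renderSpot(chB, cen[1], cen[2], sB, punctaB@peakIntensity)
    truth[[length(truth) + 1L]] <- data.frame(
      cell_id = 1L, channel = punctaB@role, row = cen[1], col = cen[2],
      radius_um = rB, sigma_px = sB, domain = NA_character_,
      f = punctaB@f, mode = "uniform", pair_id = NA_integer_)
  }

  channels <- list(nucleus = matrix(0, nr, nc))
  channels$nucleus[nmask] <- 180
  channels[[punctaA@role]] <- chA
  channels[[punctaB@role]] <- chB
  channels <- lapply(channels, applyNoise, spec = spec)
  scene <- new("TissueScene", channels = channels,
               pixelSize = spec@pixelSize,
               metadata = list(generator = "generateCulturedCell",
                               seed = spec@seed,
                               colocFraction = colocFraction))
  list(scene = scene, roi = roi, truth = do.call(rbind, truth))
}
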