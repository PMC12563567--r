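#' Project a stack of focal planes into one image
#'
#' Consecutive focal planes of one channel are merged into a single 2D
#' image, by per-pixel maximum (default) or mean.
#'
#' @param planes list of equally shaped numeric matrices.
#' @param method "max" or "mean".
#' @return one numeric matrix.
#' @examples
#' planes <- replicate(11, matrix(runif(64), 8, 8), simplify = FALSE)
#' proj <- projectStack(planes, method = "mean")
#' @export
projectStack <- function(planes, method = c("max", "mean")) {
  method <- match.arg(method)
  if (length(planes) < 1L) stop("need at least one plane")
  ref <- dim(planes[[1]])
  for (i in seq_along(planes)) {
    if (!identical(dim(planes[[i]]), ref)) {
      stop("plane ", i, " has shape ", paste(dim(planes[[i]]), collapse = "x"),
           ", expected ", paste(ref, collapse = "x"))
    }
  }
  if (method == "max") {
    Reduce(pmax, planes)
  } else {
    Reduce(`+`, planes) / length(planes)
  }
}

# intensity scale used when writing/reading 16-bit TIFF pages
.TIFF_MAX <- 65535

#' Write a scene (and optional masks / ground truth) to disk
#'
#' The channel stack is written as one multi-page 16-bit TIFF (one page per
#' channel, in the scene's channel order), with a YAML sidecar documenting
#' channel order and pixel size. Cell and nucleus masks are written as
#' 16-bit label TIFFs, the ground truth as CSV. Integer intensities in
#' [0, 65535] round-trip exactly.
#'
#' @param scene a [TissueScene-class].
#' @param dir output directory (created if missing).
#' @param rois optional list of [CellROI-class]; written as `cells.tif` and
#'   `nuclei.tif` label maps plus `rois.csv` with the per-cell flags.
#' @param truth optional ground-truth data.frame, written as `truth.csv`.
#' @param name base name for the image stack (default "scene").
#' @return invisibly, the paths written.
#' @export
writeScene <- function(scene, dir, rois = NULL, truth = NULL,
                       name = "scene") {
  stopifnot(is(scene, "TissueScene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  imgPath <- file.path(dir, paste0(name, ".tif"))
  pages <- lapply(scene@channels, function(ch) ch / .TIFF_MAX)
  tiff::writeTIFF(pages, imgPath, bits.per.sample = 16L)
  metaPath <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(list(channels = as.list(names(scene@channels)),
                        pixel_size_um = scene@pixelSize,
                        intensity_max = .TIFF_MAX),
                   metaPath)
  paths <- c(image = imgPath, metadata = metaPath)

  if (!is.null(rois)) {
    d <- dim(scene@channels[[1]])
    cellLab <- matrix(0, d[1], d[2])
    nucLab <- matrix(0, d[1], d[2])
    flags <- do.call(rbind, lapply(rois, function(r) {
      data.frame(cell_id = r@cellId, clone = r@cloneStatus,
                 tissue_edge = r@tissueEdge,
                 nucleus_in_plane = r@nucleusInPlane)
    }))
    for (r in rois) {
      cellLab[r@cellMask] <- r@cellId
      nucLab[r@nucleusMask] <- r@cellId
    }
    cellsPath <- file.path(dir, "cells.tif")
    nucPath <- file.path(dir, "nuclei.tif")
    tiff::writeTIFF(cellLab / .TIFF_MAX, cellsPath, bits.per.sample = 16L)
    tiff::writeTIFF(nucLab / .TIFF_MAX, nucPath, bits.per.sample = 16L)
    write.csv(flags, file.path(dir, "rois.csv"), row.names = FALSE)
    paths <- c(paths, cells = cellsPath, nuclei = nucPath,
               rois = file.path(dir, "rois.csv"))
  }
  if (!is.null(truth)) {
    truthPath <- file.path(dir, "truth.csv")
    write.csv(truth, truthPath, row.names = FALSE)
    paths <- c(paths, truth = truthPath)
  }
  invisible(paths)
}

#' Load a multi-page TIFF as a TissueScene
#'
#' @param path multi-page TIFF, one page per channel.
#' @param channelMap character vector of channel roles, one per page, in
#'   page order; required roles for downstream analysis are at least
#'   "nucleus" plus one puncta channel.
#' @param pixelSize numeric(1), micrometres per pixel.
#' @param requiredRoles roles that must be present (default "nucleus").
#' @return a [TissueScene-class]; intensities are rescaled back to the
#'   integer [0, 65535] range.
#' @export
loadScene <- function(path, channelMap, pixelSize,
                      requiredRoles = "nucleus") {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(channelMap) != length(pages)) {
    stop("channelMap names ", length(channelMap), " channels but the TIFF ",
         "holds ", length(pages), " pages")
  }
  missing <- setdiff(requiredRoles, channelMap)
  if (length(missing)) {
    stop("channelMap is missing required role(s): ",
         paste(missing, collapse = ", "))
  }
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # tolerate grayscale-as-RGB
    round(p * .TIFF_MAX)
  })
  names(channels) <- channelMap
  new("TissueScene", channels = channels, pixelSize = pixelSize,
      metadata = list(source = path))
}

#' Load cell/nucleus label maps as CellROI objects
#'
#' @param cellsPath,nucleiPath 16-bit label TIFFs as written by
#'   [writeScene()] (label = cell id).
#' @param flags optional data.frame with columns `cell_id`, `clone`,
#'   `tissue_edge`, `nucleus_in_plane` (as written to `rois.csv`); defaults
#'   to all-TRUE flags.
#' @return list of [CellROI-class].
#' @export
loadROIs <- function(cellsPath, nucleiPath, flags = NULL) {
  cellLab <- round(tiff::readTIFF(cellsPath) * .TIFF_MAX)
  nucLab <- round(tiff::readTIFF(nucleiPath) * .TIFF_MAX)
  ids <- sort(setdiff(unique(as.vector(cellLab)), 0))
  lapply(ids, function(i) {
    fl <- if (!is.null(flags) && i %in% flags$cell_id) {
      flags[flags$cell_id == i, ]
    } else {
      data.frame(clone = TRUE, tissue_edge = FALSE, nucleus_in_plane = TRUE)
    }
    new("CellROI", cellId = as.integer(i),
        cellMask = cellLab == i, nucleusMask = nucLab == i,
        cloneStatus = as.logical(fl$clone),
        tissueEdge = as.logical(fl$tissue_edge),
        nucleusInPlane = as.logical(fl$nucleus_in_plane))
  })
}

#' Write per-cell / per-structure result tables as CSV
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeResults <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Build generator specs from a YAML configuration
#'
#' The configuration mirrors the constructor arguments: a `scene` block
#' (fields of [sceneSpec()]) and a `puncta` list (fields of
#' [punctaSpec()]).
#'
#' @param path YAML file.
#' @return list with `spec` (a [SceneSpec-class]) and `puncta` (list of
#'   [PunctaSpec-class]).
#' @export
sceneFromConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- do.call(sceneSpec, cfg$scene %||% list())
  puncta <- lapply(cfg$puncta %||% list(),
                   function(p) do.call(punctaSpec, p))
  list(spec = spec, puncta = puncta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
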