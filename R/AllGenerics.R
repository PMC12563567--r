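#' Accessors for PeriPos classes
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param object a PeriPos object.
#' @param role character(1), a channel role held by the scene.
#' @return `pixelSize` returns the pixel size in micrometres; `channelNames`
#'   the channel roles; `getChannel` one intensity matrix; `cellMask`,
#'   `nucleusMask` and `cytoplasmMask` logical matrices; `cloneStatus` a
#'   logical flag; `structureTable` the per-structure data.frame;
#'   `labelMap` an integer label matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("getChannel", function(object, role) standardGeneric("getChannel"))
#' @rdname accessors
#' @export
setGeneric("cellMask", function(object) standardGeneric("cellMask"))
#' @rdname accessors
#' @export
setGeneric("nucleusMask", function(object) standardGeneric("nucleusMask"))
#' @rdname accessors
#' @export
setGeneric("cytoplasmMask", function(object) standardGeneric("cytoplasmMask"))
#' @rdname accessors
#' @export
setGeneric("cloneStatus", function(object) standardGeneric("cloneStatus"))
#' @rdname accessors
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("structureTable", function(object) standardGeneric("structureTable"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("perinuclearMask", function(object) standardGeneric("perinuclearMask"))
#' @rdname accessors
#' @export
setGeneric("peripheralMask", function(object) standardGeneric("peripheralMask"))
#' @rdname accessors
#' @export
setGeneric("splitDistance", function(object) standardGeneric("splitDistance"))
#' @rdname accessors
#' @export
setGeneric("indexValue", function(object) standardGeneric("indexValue"))

#' @rdname accessors
setMethod("pixelSize", "TissueScene", function(object) object@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "SceneSpec", function(object) object@pixelSize)
#' @rdname accessors
setMethod("channelNames", "TissueScene",
          function(object) names(object@channels))
#' @rdname accessors
setMethod("getChannel", "TissueScene", function(object, role) {
  if (!role %in% names(object@channels)) {
    stop("scene has no channel with role '", role, "' (available: ",
         paste(names(object@channels), collapse = ", "), ")")
  }
  object@channels[[role]]
})
#' @rdname accessors
setMethod("cellMask", "CellROI", function(object) object@cellMask)
#' @rdname accessors
setMethod("nucleusMask", "CellROI", function(object) object@nucleusMask)
#' @rdname accessors
setMethod("cytoplasmMask", "CellROI",
          function(object) object@cellMask & !object@nucleusMask)
#' @rdname accessors
setMethod("cloneStatus", "CellROI", function(object) object@cloneStatus)
#' @rdname accessors
setMethod("cellId", "CellROI", function(object) object@cellId)
#' @rdname accessors
setMethod("cellId", "StructureSet", function(object) object@cellId)
#' @rdname accessors
setMethod("structureTable", "StructureSet", function(object) object@stats)
#' @rdname accessors
setMethod("labelMap", "StructureSet", function(object) object@labelMap)
#' @rdname accessors
setMethod("perinuclearMask", "DomainPartition",
          function(object) object@perinuclear)
#' @rdname accessors
setMethod("peripheralMask", "DomainPartition",
          function(object) object@peripheral)
#' @rdname accessors
setMethod("splitDistance", "DomainPartition",
          function(object) object@splitDistance)
#' @rdname accessors
setMethod("indexValue", "DistributionResult",
          function(object) if (object@defined) object@D else NA_real_)
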