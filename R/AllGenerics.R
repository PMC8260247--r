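#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname accessors
#' @export
setGeneric("regionNames", function(x, ...) standardGeneric("regionNames"))

#' @rdname accessors
#' @export
setGeneric("regionRole", function(x, region) standardGeneric("regionRole"))

#' @rdname accessors
#' @export
setGeneric("regionCategory",
           function(x, region) standardGeneric("regionCategory"))

#' @rdname accessors
#' @export
setGeneric("regionVoxels", function(x, region, ...)
  standardGeneric("regionVoxels"))

#' @rdname accessors
#' @export
setGeneric("nRuns", function(x) standardGeneric("nRuns"))

#' @rdname accessors
#' @export
setGeneric("runSeries", function(x, run) standardGeneric("runSeries"))

#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' @rdname accessors
#' @export
setGeneric("meanZ", function(x) standardGeneric("meanZ"))

#' @rdname accessors
#' @export
setGeneric("voxelIndices", function(x) standardGeneric("voxelIndices"))

#' @rdname accessors
#' @export
setGeneric("selectionMode", function(x) standardGeneric("selectionMode"))

#' @rdname accessors
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))

#' @rdname accessors
#' @export
setGeneric("retentionRate", function(x) standardGeneric("retentionRate"))

#' @rdname accessors
#' @export
setGeneric("pairVoxelSets", function(x, i) standardGeneric("pairVoxelSets"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
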