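#' Accessors for connsel classes
#'
#' Small accessor functions exposing the slots downstream code needs,
#' so user code never reaches into \code{@} slots directly.
#'
#' @param x an object of the documented class.
#' @param region a region name.
#' @param run a run index.
#' @param i a pair index (for \code{pairVoxelSets}).
#' @param linear logical; return linear grid indices instead of an n-by-3
#'   coordinate matrix.
#' @param ... unused.
#' @name accessors
NULL

#' Convert voxel coordinates to linear grid indices
#'
#' @param coords integer matrix of voxel coordinates (n by 3).
#' @param dims integer(3) grid dimensions.
#' @return integer vector of linear (column-major) indices.
#' @export
linearIndex <- function(coords, dims) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  as.integer(coords[, 1L] + (coords[, 2L] - 1L) * dims[1L] +
    (coords[, 3L] - 1L) * dims[1L] * dims[2L])
}

#' Convert linear grid indices back to voxel coordinates
#'
#' @param idx integer vector of linear indices.
#' @param dims integer(3) grid dimensions.
#' @return integer matrix of voxel coordinates (n by 3).
#' @export
gridCoords <- function(idx, dims) {
  idx <- as.integer(idx) - 1L
  x <- idx %% dims[1L]
  y <- (idx %/% dims[1L]) %% dims[2L]
  z <- idx %/% (dims[1L] * dims[2L])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

#' @rdname accessors
#' @export
setMethod("gridDims", "RegionLayout", function(x) x@gridDims)

#' @rdname accessors
#' @export
setMethod("regionNames", "RegionLayout", function(x, ...) names(x@regions))

#' @rdname accessors
#' @export
setMethod("regionRole", "RegionLayout",
          function(x, region) unname(x@roles[region]))

#' @rdname accessors
#' @export
setMethod("regionCategory", "RegionLayout",
          function(x, region) unname(x@categories[region]))

#' @rdname accessors
#' @export
setMethod("regionVoxels", "RegionLayout",
  function(x, region, linear = TRUE) {
    co <- x@regions[[region]]
    if (is.null(co)) stop("unknown region: ", region)
    if (linear) linearIndex(co, x@gridDims) else co
  })

#' Gray-matter voxels of a layout
#'
#' @param x a \linkS4class{RegionLayout}.
#' @param linear logical; linear indices or coordinates.
#' @return voxel indices or coordinates of the gray mask.
#' @export
grayVoxels <- function(x, linear = TRUE) {
  if (linear) linearIndex(x@gray, x@gridDims) else x@gray
}

#' Non-gray (white-matter proxy) voxels of a layout
#'
#' @inheritParams grayVoxels
#' @return voxel indices or coordinates of the non-gray set.
#' @export
whiteVoxels <- function(x, linear = TRUE) {
  if (linear) linearIndex(x@white, x@gridDims) else x@white
}

#' Target-region names of a layout
#'
#' @param x a \linkS4class{RegionLayout}.
#' @return character vector of regions with role \code{"target"}.
#' @export
targetRegions <- function(x) names(x@roles)[x@roles == "target"]

#' Same-category seed regions for a target region
#'
#' All other regions (targets or dedicated seeds) sharing the target's
#' category; their activation-defined voxels supply the connectivity
#' criterion.
#'
#' @param x a \linkS4class{RegionLayout}.
#' @param target name of the target region.
#' @return character vector of seed-region names.
#' @export
seedRegionsFor <- function(x, target) {
  cat <- regionCategory(x, target)
  nm <- regionNames(x)
  nm[nm != target & x@categories[nm] == cat]
}

#' @rdname accessors
#' @export
setMethod("nRuns", "SubjectDataset", function(x) length(x@runs))

#' @rdname accessors
#' @export
setMethod("nRuns", "DesignSpec", function(x) length(x@runs))

#' @rdname accessors
#' @export
setMethod("runSeries", "SubjectDataset", function(x, run) x@runs[[run]])

#' @rdname accessors
#' @export
setMethod("trSeconds", "SubjectDataset", function(x) x@trSeconds)

#' @rdname accessors
#' @export
setMethod("trSeconds", "DesignSpec", function(x) x@trSeconds)

#' @rdname accessors
#' @export
setMethod("designMatrix", "DesignMatrix", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("conditionNames", "DesignMatrix", function(x) x@conditionNames)

#' @rdname accessors
#' @export
setMethod("conditionNames", "DesignSpec", function(x) x@conditions)

#' @rdname accessors
#' @export
setMethod("conditionNames", "RunStatMaps", function(x) x@conditionNames)

#' @rdname accessors
#' @export
setMethod("meanZ", "ConnectivityProfile", function(x) x@meanZ)

#' @rdname accessors
#' @export
setMethod("voxelIndices", "VoxelSet", function(x) x@indices)

#' @rdname accessors
#' @export
setMethod("voxelIndices", "SubjectDataset", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("selectionMode", "VoxelSet", function(x) x@mode)

#' @rdname accessors
#' @export
setMethod("nRetained", "MatchedPairSet", function(x) nrow(x@strong))

#' @rdname accessors
#' @export
setMethod("retentionRate", "MatchedPairSet",
          function(x) nrow(x@strong) / x@nDraws)

#' @rdname accessors
#' @export
setMethod("pairVoxelSets", "MatchedPairSet", function(x, i) {
  if (i < 1L || i > nrow(x@strong)) stop("pair index out of range")
  list(
    strong = new("VoxelSet", indices = as.integer(x@strong[i, ]), k = x@k,
                 mode = "matched_strong", foldId = x@foldId,
                 contrastUsed = x@contrastUsed),
    weak = new("VoxelSet", indices = as.integer(x@weak[i, ]), k = x@k,
               mode = "matched_weak", foldId = x@foldId,
               contrastUsed = x@contrastUsed)
  )
})

#' @rdname accessors
#' @export
setMethod("groundTruth", "SubjectDataset", function(x) x@truth)

setMethod("show", "RegionLayout", function(object) {
  cat("RegionLayout on a", paste(object@gridDims, collapse = " x "),
      "grid\n")
  for (r in regionNames(object)) {
    cat(sprintf("  %-10s %-6s %-8s %5d voxels\n", r, object@roles[r],
                object@categories[r], nrow(object@regions[[r]])))
  }
  cat("  gray mask:", nrow(object@gray), "voxels; non-gray:",
      nrow(object@white), "voxels\n")
})

setMethod("show", "EffectSpec", function(object) {
  cat("EffectSpec: coupling", object@couplingStrength,
      "| fracInformative", object@fracInformative,
      "| patternSnr", object@patternSnr,
      "| activationGain", object@activationGain,
      "| noiseSd", object@noiseSd,
      "| baseline", object@baseline,
      "| seed", object@seed, "\n")
})

setMethod("show", "SubjectDataset", function(object) {
  cat("SubjectDataset:", length(object@runs), "runs of",
      nrow(object@runs[[1]]), "volumes x", length(object@voxels),
      "voxels (TR", object@trSeconds, "s)\n")
})

setMethod("show", "ConnectivityProfile", function(object) {
  cat("ConnectivityProfile:", nrow(object@zMatrix), "target voxels x",
      ncol(object@zMatrix), "seed voxels (fold", object@foldId, ")\n")
  cat("  mean z over eligible voxels:",
      signif(mean(object@meanZ[object@eligible]), 4), "\n")
})

setMethod("show", "VoxelSet", function(object) {
  cat("VoxelSet:", object@k, "voxels, mode", object@mode,
      "(fold", object@foldId, ")\n")
})

setMethod("show", "MatchedPairSet", function(object) {
  cat("MatchedPairSet:", nrow(object@strong), "of", object@nDraws,
      "draws retained (", object@mode, "threshold, k =", object@k, ")\n")
})

setMethod("show", "GroupMap", function(object) {
  cat("GroupMap:", length(object@z), "voxels,", object@nPerm,
      "permutations;", sum(object@z > object@threshold),
      "voxels above z =", object@threshold, "\n")
})
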