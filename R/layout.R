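#' Voxels of a lattice sphere
#'
#' All integer grid coordinates within Euclidean distance \code{radius}
#' (in voxels) of a center.
#'
#' @param center integer(3) center coordinate.
#' @param radius radius in voxels.
#' @return integer matrix of coordinates, one row per voxel.
#' @export
sphereVoxels <- function(center, radius) {
  r <- ceiling(radius)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g <- g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
  sweep(g, 2L, as.integer(center), "+")
}

#' Build a region layout from sphere specifications
#'
#' Resolves spherical region specifications to voxel sets on an isotropic
#' grid and validates the geometric contract of the analysis: every
#' region lies inside the grid, every target region exceeds the minimum
#' gray-voxel count, and regions of the same category are pairwise
#' disjoint (regions of different categories are free to overlap).
#'
#' @param gridDims integer(3), voxels per axis.
#' @param regionSpecs named list; each element a list with \code{center}
#'   (integer(3)), \code{radius} (voxels), \code{role} ("target" or
#'   "seed") and \code{category}.
#' @param grayExtra optional coordinate matrix of additional gray voxels
#'   outside the named regions (e.g. searchlight territory).
#' @param white optional coordinate matrix of non-gray voxels used for
#'   the global-signal proxy; defaults to a small corner block.
#' @param minTargetVoxels minimum voxel count per target region
#'   (default 300, matching the gray-voxel floor of the target search
#'   spaces).
#' @return a \linkS4class{RegionLayout}.
#' @examples
#' ly <- makeLayout(c(20, 20, 20), list(
#'   roi = list(center = c(10, 10, 10), radius = 5, role = "target",
#'              category = "tools"),
#'   src = list(center = c(4, 4, 4), radius = 3, role = "seed",
#'              category = "tools")))
#' @export
makeLayout <- function(gridDims, regionSpecs, grayExtra = NULL,
                       white = NULL, minTargetVoxels = 300L) {
  gridDims <- as.integer(gridDims)
  stopifnot(length(gridDims) == 3L, all(gridDims >= 1L))
  if (is.null(names(regionSpecs)) || any(names(regionSpecs) == ""))
    stop("regionSpecs must be a named list")

  regions <- list(); roles <- character(); cats <- character()
  for (nm in names(regionSpecs)) {
    sp <- regionSpecs[[nm]]
    co <- sphereVoxels(unlist(sp$center), sp$radius)
    if (any(co < 1L) || any(t(co) > gridDims))
      stop("region '", nm, "' extends outside the grid")
    if (identical(sp$role, "target") && nrow(co) <= minTargetVoxels)
      stop("target region '", nm, "' has only ", nrow(co),
           " voxels (<= ", minTargetVoxels, ")")
    regions[[nm]] <- co
    roles[nm] <- sp$role
    cats[nm] <- sp$category
  }

  # same-category regions must not overlap
  nm <- names(regions)
  for (i in seq_along(nm)) for (j in seq_len(i - 1L)) {
    if (cats[nm[i]] != cats[nm[j]]) next
    ii <- linearIndex(regions[[nm[i]]], gridDims)
    jj <- linearIndex(regions[[nm[j]]], gridDims)
    if (length(intersect(ii, jj)))
      stop("same-category regions '", nm[j], "' and '", nm[i],
           "' overlap")
  }

  grayIdx <- unique(unlist(lapply(regions, linearIndex, dims = gridDims)))
  if (!is.null(grayExtra))
    grayIdx <- union(grayIdx, linearIndex(grayExtra, gridDims))
  grayIdx <- sort(grayIdx)

  if (is.null(white)) {
    wdim <- pmin(gridDims, 6L)
    white <- as.matrix(expand.grid(x = seq_len(wdim[1]),
                                   y = seq_len(wdim[2]),
                                   z = seq_len(wdim[3])))
  }
  whiteIdx <- setdiff(linearIndex(white, gridDims), grayIdx)

  new("RegionLayout", gridDims = gridDims, regions = regions,
      roles = roles, categories = cats,
      gray = gridCoords(grayIdx, gridDims),
      white = gridCoords(sort(whiteIdx), gridDims))
}

#' Default ten-region layout
#'
#' The geometry the package analyses by default: six radius-5 target
#' spheres (515 voxels each; two per category for tools, faces and
#' places) and four radius-4 distal seed spheres (257 voxels each; two
#' extra tool seeds, one face seed, one place seed), placed disjointly on
#' a 45 x 34 x 12 grid, plus a non-gray block for the global-signal
#' proxy.  Region names follow the category-preferring areas they stand
#' in for (medial fusiform, posterior middle temporal, fusiform and
#' occipital face areas, parahippocampal and occipital place areas;
#' parietal, superior-temporal and retrosplenial seeds).
#'
#' @return a \linkS4class{RegionLayout}.
#' @export
defaultLayout <- function() {
  t5 <- function(center, category)
    list(center = center, radius = 5, role = "target", category = category)
  s4 <- function(center, category)
    list(center = center, radius = 4, role = "seed", category = category)
  specs <- list(
    MFus = t5(c(6, 6, 6), "tools"),
    PMTG = t5(c(17, 6, 6), "tools"),
    FFA  = t5(c(28, 6, 6), "faces"),
    OFA  = t5(c(39, 6, 6), "faces"),
    PPA  = t5(c(6, 17, 6), "places"),
    OPA  = t5(c(17, 17, 6), "places"),
    IPL  = s4(c(28, 17, 6), "tools"),
    SPL  = s4(c(39, 17, 6), "tools"),
    STS  = s4(c(6, 28, 6), "faces"),
    RSC  = s4(c(17, 28, 6), "places")
  )
  white <- as.matrix(expand.grid(x = 28:33, y = 24:29, z = 4:9))
  makeLayout(c(45L, 34L, 12L), specs, white = white)
}

#' Compact single-category layout for searchlight and calibration work
#'
#' One target sphere and one coupled seed sphere of a single category on
#' a small grid whose entire volume (minus a non-gray corner block) is
#' gray matter, so that searchlight centers cover the whole grid.  Used
#' for null-calibration and localization studies where the full
#' ten-region geometry is unnecessarily large.
#'
#' @param gridDims integer(3) grid (default 12^3).
#' @param targetCenter,targetRadius target sphere (default radius 4, 257
#'   voxels; the >300 floor is relaxed here, see
#'   \code{minTargetVoxels}).
#' @param seedCenter,seedRadius coupled seed sphere (default radius 3,
#'   123 voxels).
#' @param category stimulus category of both regions.
#' @param minTargetVoxels passed to \code{\link{makeLayout}}; default 200
#'   for this reduced geometry.
#' @return a \linkS4class{RegionLayout}.
#' @export
compactLayout <- function(gridDims = c(12L, 12L, 12L),
                          targetCenter = c(8, 8, 8), targetRadius = 4,
                          seedCenter = c(4, 4, 4), seedRadius = 3,
                          category = "tools", minTargetVoxels = 200L) {
  gridDims <- as.integer(gridDims)
  white <- as.matrix(expand.grid(x = seq_len(3), y = seq_len(3),
                                 z = (gridDims[3] - 2L):gridDims[3]))
  whiteIdx <- linearIndex(white, gridDims)
  full <- gridCoords(setdiff(seq_len(prod(gridDims)), whiteIdx), gridDims)
  makeLayout(gridDims,
    list(target = list(center = targetCenter, radius = targetRadius,
                       role = "target", category = category),
         seed = list(center = seedCenter, radius = seedRadius,
                     role = "seed", category = category)),
    grayExtra = full, white = white, minTargetVoxels = minTargetVoxels)
}

#' Dilate a voxel set on the grid
#'
#' Morphological dilation by Euclidean distance, used to express
#' localization tolerances ("within the seed region dilated by two
#' voxels").
#'
#' @param idx integer linear indices of the set.
#' @param dims integer(3) grid dimensions.
#' @param by dilation radius in voxels.
#' @return integer linear indices of the dilated set (clipped to grid).
#' @export
dilateVoxels <- function(idx, dims, by = 2) {
  co <- gridCoords(idx, dims)
  off <- sphereVoxels(c(0L, 0L, 0L), by)
  out <- do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    sweep(co, 2L, off[i, ], "+")))
  keep <- out[, 1] >= 1 & out[, 2] >= 1 & out[, 3] >= 1 &
    out[, 1] <= dims[1] & out[, 2] <= dims[2] & out[, 3] <= dims[3]
  sort(unique(linearIndex(out[keep, , drop = FALSE], dims)))
}
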