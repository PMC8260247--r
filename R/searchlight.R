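#' Searchlight neighborhoods over the gray mask
#'
#' For every gray-matter voxel, the k nearest gray voxels by Euclidean
#' grid distance (center included), with distance ties broken by
#' ascending voxel index — a fixed-size analogue of a ~k-voxel
#' contiguous searchlight.
#'
#' @param layout a \linkS4class{RegionLayout}.
#' @param k neighborhood size (default 100).
#' @return list with \code{grayIdx} (sorted linear indices of the gray
#'   mask) and \code{neighbors} (centers-by-k matrix of positions into
#'   \code{grayIdx}; row i is the neighborhood of center
#'   \code{grayIdx[i]}).
#' @export
searchlightNeighborhoods <- function(layout, k = 100L) {
  co <- grayVoxels(layout, linear = FALSE)
  grayIdx <- linearIndex(co, gridDims(layout))
  o <- order(grayIdx)
  co <- co[o, , drop = FALSE]
  grayIdx <- grayIdx[o]
  n <- nrow(co)
  if (n < k) stop("gray mask has fewer than k voxels")
  sq <- rowSums(co^2)
  nb <- matrix(0L, n, k)
  chunk <- max(1L, floor(2e7 / n))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") -
      2 * co[s:e, , drop = FALSE] %*% t(co)
    for (i in seq_len(e - s + 1L)) {
      nb[s + i - 1L, ] <- order(d2[i, ], grayIdx)[seq_len(k)]
    }
  }
  list(grayIdx = grayIdx, neighbors = nb)
}

#' Good-seed searchlight maps for one subject
#'
#' Centers a ~k-voxel neighborhood on every gray voxel outside the
#' target region, uses the neighborhood's mean residual time course as
#' a single seed series for connectivity-based selection in the target
#' region (Fisher z per target voxel, top/bottom \code{kSelect}), and
#' scores split-half decoding with one odd/even run fold.  Target-region
#' voxels are excluded both as centers and from the seed role inside
#' neighborhoods.  The module is deterministic given the subject data.
#'
#' @param subject a \linkS4class{SubjectDataset}.
#' @param targetRegion name of the target region.
#' @param comparison character(2), the two decoded conditions.
#' @param k neighborhood size (default 100).
#' @param kSelect selected voxels per set (default 100).
#' @param neighborhoods optional precomputed
#'   \code{\link{searchlightNeighborhoods}} result (shared across
#'   subjects on a common layout).
#' @param prep optional precomputed \code{\link{prepareSubject}} result.
#' @return a \linkS4class{SearchlightMap} holding the most-connected and
#'   least-connected accuracy maps on a shared center set.
#' @export
goodSeedMaps <- function(subject, targetRegion, comparison, k = 100L,
                         kSelect = 100L, neighborhoods = NULL,
                         prep = NULL) {
  layout <- subject@layout
  if (is.null(neighborhoods))
    neighborhoods <- searchlightNeighborhoods(layout, k)
  if (is.null(prep)) prep <- prepareSubject(subject)
  grayIdx <- neighborhoods$grayIdx
  nb <- neighborhoods$neighbors

  targetIdx <- regionVoxels(layout, targetRegion)
  targetCols <- regionColumns(subject, targetRegion)
  inTarget <- grayIdx %in% targetIdx
  centers <- which(!inTarget)

  R <- do.call(rbind, prep$residuals)
  grayPos <- match(grayIdx, subject@voxels)
  if (anyNA(grayPos)) stop("gray mask has unsimulated voxels")
  Rgray <- R[, grayPos, drop = FALSE]

  # mean neighborhood series per center, target voxels removed from the
  # seed role; sparse membership matrix keeps this a single product
  rows <- t(nb[centers, , drop = FALSE])
  keep <- !inTarget[rows]
  cidx <- rep(seq_along(centers), each = k)[keep]
  ridx <- rows[keep]
  wt <- 1 / tabulate(cidx, nbins = length(centers))
  M <- Matrix::sparseMatrix(i = ridx, j = cidx, x = wt[cidx],
                            dims = c(length(grayIdx), length(centers)))
  S <- as.matrix(Rgray %*% M)

  # Fisher z of every target voxel to every center's seed series
  Tts <- R[, targetCols, drop = FALSE]
  sdT <- apply(Tts, 2, sd)
  sdS <- apply(S, 2, sd)
  eligT <- is.finite(sdT) & sdT > 0
  okS <- is.finite(sdS) & sdS > 0
  zt <- scale(Tts); zt[, !eligT] <- 0
  zs <- scale(S); zs[, !okS] <- 0
  r <- crossprod(zt, zs) / (nrow(R) - 1)
  z <- atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))

  nT <- length(targetCols)
  if (sum(eligT) < 2L * kSelect)
    stop("fewer than 2k eligible target voxels")
  elig <- which(eligT)
  idMost <- matrix(0L, length(centers), kSelect)
  idLeast <- matrix(0L, length(centers), kSelect)
  for (j in seq_along(centers)) {
    zj <- z[elig, j]
    om <- order(-zj, elig)
    idMost[j, ] <- elig[om[seq_len(kSelect)]]
    ol <- order(zj, elig)
    idLeast[j, ] <- elig[ol[seq_len(kSelect)]]
  }

  runs <- seq_len(nRuns(subject))
  splits <- list(runs[runs %% 2L == 1L], runs[runs %% 2L == 0L])
  betas <- lapply(splits, function(rr) {
    mats <- lapply(rr, function(r)
      conditionBetas(prep$statmaps[[r]])[comparison, targetCols,
                                         drop = FALSE])
    Reduce(`+`, mats) / length(mats)
  })
  accM <- subsetAccuracy(idMost, betas[[1]][1, ], betas[[1]][2, ],
                         betas[[2]][1, ], betas[[2]][2, ])
  accL <- subsetAccuracy(idLeast, betas[[1]][1, ], betas[[1]][2, ],
                         betas[[2]][1, ], betas[[2]][2, ])
  accM[!okS] <- NA_real_
  accL[!okS] <- NA_real_

  new("SearchlightMap", centers = grayIdx[centers], most = accM,
      least = accL, dims = gridDims(layout),
      targetRegion = targetRegion,
      comparison = comparisonLabel(comparison[1], comparison[2]))
}

#' Per-subject searchlight difference maps as a matrix
#'
#' Stacks most-minus-least accuracy differences across subjects on the
#' shared center set, the input expected by
#' \code{\link{signFlipGroupMap}}.
#'
#' @param maps list of \linkS4class{SearchlightMap}, one per subject,
#'   computed on a common layout.
#' @return list with \code{diffs} (subject-by-center matrix),
#'   \code{centers} and \code{dims}.
#' @export
searchlightDiffs <- function(maps) {
  centers <- maps[[1]]@centers
  for (m in maps) stopifnot(identical(m@centers, centers))
  diffs <- do.call(rbind, lapply(maps, function(m) m@most - m@least))
  list(diffs = diffs, centers = centers, dims = maps[[1]]@dims)
}
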