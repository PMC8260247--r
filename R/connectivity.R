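#' Regress task and nuisance structure out of a run
#'
#' OLS projection of every voxel's series onto the span of the task
#' design (HRF-convolved condition regressors, drift terms, intercept)
#' plus the supplied nuisance regressors; the residuals are returned.
#'
#' @param y time-by-voxel data matrix.
#' @param dm a \linkS4class{DesignMatrix} (task + drift + intercept).
#' @param nuisance optional time-by-q nuisance matrix (motion, motion
#'   derivatives, global-signal proxy).
#' @return residual time-by-voxel matrix.
#' @export
taskRegress <- function(y, dm, nuisance = NULL) {
  X <- dm@matrix
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == nrow(X))
    X <- cbind(X, nuisance)
  }
  y <- as.matrix(y)
  if (nrow(y) != nrow(X)) stop("data and design row counts differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("task-plus-nuisance design is rank deficient")
  qr.resid(qrX, y)
}

#' Zero-phase band-pass filter
#'
#' Fourier-domain band-pass with unit passband gain and raised-cosine
#' transitions (zero phase by construction).  The gain is 1 inside
#' \code{[lowHz, highHz]}, rolls off to 0 below \code{lowHz/2} and above
#' \code{1.5 highHz}, and is exactly 0 at DC, so constant series map to
#' (numerically) zero.
#'
#' @param y numeric vector or time-by-voxel matrix.
#' @param lowHz,highHz passband edges in Hz (defaults 0.01 and 0.1).
#' @param trSeconds sampling interval in seconds.
#' @return filtered series, same shape as \code{y}.
#' @export
bandpassFilter <- function(y, lowHz = 0.01, highHz = 0.1, trSeconds) {
  stopifnot(lowHz > 0, highHz > lowHz)
  nyquist <- 1 / (2 * trSeconds)
  if (highHz >= nyquist)
    stop("highHz must be below the Nyquist frequency ", nyquist, " Hz")
  vec <- is.null(dim(y))
  y <- as.matrix(y)
  n <- nrow(y)
  f <- seq(0, n - 1) / (n * trSeconds)
  f <- pmin(f, 1 / trSeconds - f)

  ramp <- function(x) 0.5 - 0.5 * cos(pi * pmin(pmax(x, 0), 1))
  gain <- ramp((f - lowHz / 2) / (lowHz / 2)) *
    (1 - ramp((f - highHz) / (0.25 * highHz)))
  gain[f < 1e-12] <- 0

  out <- Re(mvfft(mvfft(y) * gain, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

#' Voxelwise connectivity of target voxels to seed voxels
#'
#' Pearson correlation of every target-region voxel with every seed
#' voxel over the supplied (already concatenated) time points, Fisher-z
#' transformed; \code{meanZ} is the per-target-voxel mean across all
#' seed voxels and is the selection score.  Correlations of magnitude 1
#' are clipped to \code{1 - 1e-7} before \code{atanh} so z stays finite.
#' Zero-variance target voxels are flagged ineligible (their z values
#' are \code{NA}); zero-variance seed voxels are dropped from the mean.
#'
#' @param targetTs time-by-voxel matrix of target-region residual series.
#' @param seedTs time-by-voxel matrix, or named list of matrices (one
#'   per seed region, concatenated internally).
#' @param foldId integer fold label carried through for provenance.
#' @return a \linkS4class{ConnectivityProfile}.
#' @export
connectivityProfile <- function(targetTs, seedTs, foldId = NA_integer_) {
  if (is.list(seedTs)) seedTs <- do.call(cbind, seedTs)
  targetTs <- as.matrix(targetTs)
  seedTs <- as.matrix(seedTs)
  stopifnot(nrow(targetTs) == nrow(seedTs))
  n <- nrow(targetTs)

  sdT <- apply(targetTs, 2, sd)
  sdS <- apply(seedTs, 2, sd)
  eligT <- is.finite(sdT) & sdT > 0
  eligS <- is.finite(sdS) & sdS > 0

  zt <- scale(targetTs[, , drop = FALSE])
  zs <- scale(seedTs[, , drop = FALSE])
  zt[, !eligT] <- 0
  zs[, !eligS] <- 0
  r <- crossprod(zt, zs) / (n - 1)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[!eligT, ] <- NA_real_
  z[, !eligS] <- NA_real_

  meanZ <- rowMeans(z[, eligS, drop = FALSE])
  new("ConnectivityProfile", zMatrix = z, meanZ = meanZ,
      foldId = as.integer(foldId), eligible = eligT)
}

# column positions of a region's voxels within a subject's data matrices
regionColumns <- function(subject, region) {
  pos <- match(regionVoxels(subject@layout, region), subject@voxels)
  if (anyNA(pos)) stop("region '", region, "' has unsimulated voxels")
  pos
}

#' Task-regressed, band-passed residual series of a subject
#'
#' Per run: regress out the HRF-convolved task regressors, drift terms,
#' the six motion series and their first-order temporal derivatives, and
#' a global-signal proxy (the mean series over the layout's non-gray
#' voxels), then band-pass the residuals to 0.01-0.1 Hz.  These
#' residuals are the substrate of every connectivity computation.
#'
#' @param subject a \linkS4class{SubjectDataset}.
#' @param hpCutoffSeconds high-pass cutoff of the task design
#'   (default 256).
#' @param lowHz,highHz band-pass edges (defaults 0.01 and 0.1 Hz).
#' @return list of residual time-by-voxel matrices, one per run.
#' @export
subjectResiduals <- function(subject, hpCutoffSeconds = 256,
                             lowHz = 0.01, highHz = 0.1) {
  whitePos <- match(whiteVoxels(subject@layout), subject@voxels)
  whitePos <- whitePos[!is.na(whitePos)]
  lapply(seq_len(nRuns(subject)), function(r) {
    y <- subject@runs[[r]]
    dm <- buildDesignMatrix(subject@design, r,
                            hpCutoffSeconds = hpCutoffSeconds)
    mot <- subject@motion[[r]]
    dmot <- rbind(0, diff(mot))
    glob <- if (length(whitePos)) rowMeans(y[, whitePos, drop = FALSE])
    nuis <- cbind(mot, dmot, glob)
    res <- taskRegress(y, dm, nuis)
    bandpassFilter(res, lowHz, highHz, subject@trSeconds)
  })
}
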