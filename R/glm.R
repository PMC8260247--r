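#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a gamma response peaking near 5 s
#' minus a scaled gamma undershoot peaking near 16 s (no time or
#' dispersion derivatives), sampled at the repetition time and
#' peak-normalized to 1.
#'
#' @param trSeconds sampling interval in seconds.
#' @param durationSeconds kernel length (default 32 s).
#' @param peakDelay,undershootDelay gamma shape parameters of the
#'   response and undershoot (defaults 6 and 16).
#' @param peakDispersion,undershootDispersion gamma scale parameters
#'   (defaults 1).
#' @param undershootRatio undershoot amplitude relative to the peak
#'   (default 1/6).
#' @return numeric kernel sampled at \code{0, tr, 2 tr, ...}.
#' @examples
#' h <- canonicalHrf(0.1)
#' (which.max(h) - 1) * 0.1  # peaks near 5 s
#' @export
canonicalHrf <- function(trSeconds, durationSeconds = 32,
                         peakDelay = 6, undershootDelay = 16,
                         peakDispersion = 1, undershootDispersion = 1,
                         undershootRatio = 1 / 6) {
  stopifnot(trSeconds > 0)
  t <- seq(0, durationSeconds, by = trSeconds)
  h <- dgamma(t, shape = peakDelay / peakDispersion,
              scale = peakDispersion) -
    undershootRatio * dgamma(t, shape = undershootDelay /
                               undershootDispersion,
                             scale = undershootDispersion)
  h / max(h)
}

# boxcar (1 during stimulus) sampled at volume acquisition times
conditionBoxcar <- function(events, condition, nVolumes, trSeconds) {
  tvol <- (seq_len(nVolumes) - 1L) * trSeconds
  box <- numeric(nVolumes)
  ev <- events[events$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(ev)))
    box[tvol >= ev$onset[i] - 1e-9 &
          tvol < ev$onset[i] + ev$duration[i] - 1e-9] <- 1
  box
}

# HRF-convolved condition regressors for one run (time x condition)
taskRegressors <- function(design, run, hrf = NULL) {
  nVol <- design@nVolumes
  tr <- design@trSeconds
  if (is.null(hrf)) hrf <- canonicalHrf(tr)
  ev <- design@runs[[run]]
  if (any(ev$onset + ev$duration > nVol * tr + 1e-9))
    stop("a block extends past the end of run ", run)
  X <- vapply(design@conditions, function(cn) {
    convolve(conditionBoxcar(ev, cn, nVol, tr), rev(hrf),
             type = "open")[seq_len(nVol)]
  }, numeric(nVol))
  colnames(X) <- design@conditions
  X
}

# discrete-cosine drift basis: components with period 2T/k above the
# high-pass cutoff (SPM convention; empty when cutoff > twice run length)
driftBasis <- function(nVolumes, trSeconds, hpCutoffSeconds) {
  total <- nVolumes * trSeconds
  K <- floor(2 * total / hpCutoffSeconds + 1e-9)
  if (K < 1L) return(matrix(numeric(0), nrow = nVolumes, ncol = 0L))
  t <- seq_len(nVolumes) - 1L
  D <- vapply(seq_len(K), function(k)
    cos(pi * k * (2 * t + 1) / (2 * nVolumes)), numeric(nVolumes))
  colnames(D) <- paste0("drift", seq_len(K))
  D
}

#' Build a first-level design matrix
#'
#' One HRF-convolved regressor per condition, discrete-cosine drift
#' columns implementing the high-pass cutoff (components slower than the
#' cutoff are spanned by the basis and thereby removed from the condition
#' estimates), optional six motion regressors, and an intercept.
#'
#' @param design a \linkS4class{DesignSpec}.
#' @param run run index.
#' @param motion optional time-by-6 motion matrix.
#' @param hpCutoffSeconds high-pass cutoff in seconds (default 256).
#' @param hrf optional HRF kernel sampled at the TR; defaults to
#'   \code{\link{canonicalHrf}}.
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(design, run, motion = NULL,
                              hpCutoffSeconds = 256, hrf = NULL) {
  X <- taskRegressors(design, run, hrf)
  D <- driftBasis(design@nVolumes, design@trSeconds, hpCutoffSeconds)
  parts <- list(X, D)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == design@nVolumes)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    parts <- c(parts, list(motion))
  }
  parts <- c(parts, list(intercept = matrix(1, design@nVolumes, 1,
                                            dimnames = list(NULL,
                                                            "intercept"))))
  M <- do.call(cbind, parts)
  new("DesignMatrix", matrix = M, conditionNames = design@conditions,
      trSeconds = design@trSeconds)
}

#' Fit the run-wise GLM by ordinary least squares
#'
#' @param y time-by-voxel data matrix for one run.
#' @param dm a \linkS4class{DesignMatrix} with matching row count.
#' @return a \linkS4class{RunStatMaps}.
#' @export
fitGlmRun <- function(y, dm) {
  X <- dm@matrix
  y <- as.matrix(y)
  if (nrow(y) != nrow(X))
    stop("data rows (", nrow(y), ") do not match design rows (",
         nrow(X), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrX, y)
  res <- y - X %*% coef
  df <- nrow(X) - ncol(X)
  new("RunStatMaps", coef = coef, conditionNames = dm@conditionNames,
      residualDf = as.integer(df),
      residualVariance = colSums(res^2) / df,
      xtxInv = chol2inv(qr.R(qrX)))
}

#' Condition betas of a fitted run
#'
#' @param sm a \linkS4class{RunStatMaps}.
#' @return condition-by-voxel beta matrix.
#' @export
conditionBetas <- function(sm) {
  sm@coef[sm@conditionNames, , drop = FALSE]
}

#' Category-preference contrast weights
#'
#' Weights of 1 on the target intact category and -1/3 on the three
#' other intact categories; phase-scrambled conditions are weighted 0.
#'
#' @param category one of the intact categories.
#' @param conditions full condition set (defaults to the canonical one).
#' @return named numeric weight vector over conditions.
#' @export
categoryContrast <- function(category, conditions = ALL_CONDITIONS) {
  stopifnot(category %in% INTACT_CONDITIONS)
  w <- setNames(numeric(length(conditions)), conditions)
  w[category] <- 1
  w[setdiff(INTACT_CONDITIONS, category)] <- -1 / 3
  w
}

#' Pairwise condition contrast weights
#'
#' @param a,b condition names contrasted as \code{a > b}.
#' @param conditions full condition set.
#' @return named numeric weight vector over conditions.
#' @export
pairContrast <- function(a, b, conditions = ALL_CONDITIONS) {
  w <- setNames(numeric(length(conditions)), conditions)
  w[a] <- 1
  w[b] <- -1
  w
}

#' Contrast t map for a fitted run
#'
#' Computes \code{t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)} per voxel.
#' Voxels with zero residual variance have no defined t and are returned
#' as \code{NA} (downstream selection treats them as ineligible).
#'
#' @param sm a \linkS4class{RunStatMaps}.
#' @param weights named weight vector over conditions (see
#'   \code{\link{categoryContrast}}), or an unnamed vector of length
#'   equal to the condition count.
#' @return numeric per-voxel t values.
#' @export
contrastTmap <- function(sm, weights) {
  cn <- sm@conditionNames
  if (is.null(names(weights))) {
    if (length(weights) != length(cn))
      stop("weight vector length must equal condition count")
    names(weights) <- cn
  }
  cfull <- setNames(numeric(nrow(sm@coef)), rownames(sm@coef))
  cfull[names(weights)] <- weights
  if (all(abs(cfull) < 1e-15))           # null contrast: t = 0 everywhere
    return(numeric(ncol(sm@coef)))
  num <- drop(crossprod(cfull, sm@coef))
  cvar <- drop(crossprod(cfull, sm@xtxInv %*% cfull))
  den2 <- sm@residualVariance * cvar
  t <- rep(NA_real_, length(num))        # zero residual variance: flagged
  ok <- is.finite(den2) & den2 > 0 & sm@residualVariance > 1e-12
  t[ok] <- num[ok] / sqrt(den2[ok])
  t
}

# mean contrast t over the runs of a split (NA propagates)
splitTmap <- function(statmaps, runs, weights) {
  ts <- vapply(runs, function(r) contrastTmap(statmaps[[r]], weights),
               numeric(ncol(statmaps[[runs[1]]]@coef)))
  rowMeans(ts)
}
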