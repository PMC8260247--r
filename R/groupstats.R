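#' Paired t test
#'
#' Standard paired t on the within-subject differences, with listwise
#' deletion of incomplete pairs.
#'
#' @param a,b numeric vectors of equal length.
#' @return list with \code{t}, \code{df} and two-tailed \code{p}.
#' @export
pairedT <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  if (length(d) < 2L) stop("need at least 2 complete pairs")
  s <- sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t = 0, df = length(d) - 1L, p = 1))
    stop("zero-variance nonzero differences")
  }
  t <- mean(d) / (s / sqrt(length(d)))
  df <- length(d) - 1L
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise alpha.
#' @param m number of comparisons.
#' @return the per-test threshold \code{alpha / m}.
#' @export
bonferroniThreshold <- function(alpha, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Repeated-measures ANOVA with partial eta squared
#'
#' Fully within-subject ANOVA over up to three crossed factors.
#' Subjects with missing cells are dropped (listwise); each effect is
#' tested against its own subject-by-effect error stratum and reported
#' with uncorrected degrees of freedom and partial eta squared
#' (SS_effect / (SS_effect + SS_error)).
#'
#' @param table long-format data frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector (1-3) of within-subject factor
#'   columns.
#' @param subject name of the subject-identifier column.
#' @return data frame with one row per effect: term, F, df1, df2, p,
#'   petaSq, and the retained subject count as an attribute
#'   \code{"nSubjects"}.
#' @export
rmAnova <- function(table, dv = "accuracy", within, subject = "subject") {
  stopifnot(length(within) >= 1L, length(within) <= 3L)
  d <- table[, c(subject, within, dv)]
  names(d) <- c(".subj", paste0(".f", seq_along(within)), ".y")
  d <- d[complete.cases(d) & is.finite(d$.y), ]
  fcols <- paste0(".f", seq_along(within))
  for (f in c(".subj", fcols)) d[[f]] <- factor(d[[f]])

  # collapse replicate cells (e.g. folds), then drop incomplete subjects
  d <- aggregate(.y ~ ., data = d, FUN = mean)
  nCells <- prod(vapply(d[fcols], nlevels, 1L))
  cnt <- table(d$.subj)
  keepSubj <- names(cnt)[cnt == nCells]
  d <- d[d$.subj %in% keepSubj, ]
  d$.subj <- droplevels(d$.subj)
  if (nlevels(d$.subj) < 2L) stop("fewer than 2 complete subjects")

  rhs <- paste(fcols, collapse = " * ")
  form <- as.formula(paste0(".y ~ ", rhs, " + Error(.subj/(", rhs, "))"))
  fit <- aov(form, data = d)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    ierr <- which(rn == "Residuals")
    if (!length(ierr) || length(rn) < 2L) next
    sseErr <- tab[ierr, "Sum Sq"]
    dfErr <- tab[ierr, "Df"]
    for (i in setdiff(seq_along(rn), ierr)) {
      ss <- tab[i, "Sum Sq"]
      Fv <- if (ss <= 1e-12 && sseErr <= 1e-12) 0 else tab[i, "F value"]
      pv <- if (ss <= 1e-12 && sseErr <= 1e-12) 1 else tab[i, "Pr(>F)"]
      term <- rn[i]
      for (j in seq_along(within))
        term <- gsub(paste0(".f", j), within[j], term, fixed = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        term = term, F = Fv, df1 = tab[i, "Df"], df2 = dfErr, p = pv,
        petaSq = if (ss + sseErr > 0) ss / (ss + sseErr) else 0)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "nSubjects") <- nlevels(d$.subj)
  res
}

#' Threshold-free cluster enhancement
#'
#' Enhances the positive part of a statistic map by integrating cluster
#' extent and height over all thresholds:
#' \code{sum_h extent(h)^E * h^H * dh}, with clusters defined by face
#' (6-)connectivity among suprathreshold voxels and
#' \code{dh = max(map)/nSteps}.
#'
#' @param values numeric statistic per mask voxel.
#' @param dims integer(3) grid dimensions.
#' @param maskIdx linear grid indices of the mask voxels (same order as
#'   \code{values}).
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param nSteps number of integration steps (default 100).
#' @return enhanced values, same order as the input.
#' @export
tfce <- function(values, dims, maskIdx, E = 0.5, H = 2, nSteps = 100L) {
  stopifnot(length(values) == length(maskIdx))
  .tfceCpp(as.numeric(values), as.integer(dims), as.integer(maskIdx),
           E, H, as.integer(nSteps))
}

#' Sign-flip permutation group map with TFCE and max-statistic FWE
#'
#' Observed statistic: the one-sample t map of the subject difference
#' maps (mean over SE), TFCE-enhanced.  Null: the same statistic under
#' random per-subject sign flips; each voxel's FWE-corrected p is the
#' proportion of permutation maxima reaching its observed enhanced
#' value, converted to a z score and thresholded.
#'
#' @param diffs subject-by-voxel matrix of difference maps (e.g.
#'   most-connected minus least-connected searchlight accuracy).
#' @param dims integer(3) grid dimensions.
#' @param maskIdx linear grid indices of the columns of \code{diffs}.
#' @param nPerm number of sign-flip permutations (default 10000; fewer
#'   than 100 triggers a warning about unstable tails).
#' @param seed RNG seed for the flips.
#' @param E,H,nSteps TFCE parameters (defaults 0.5, 2, 100).
#' @param zThreshold survival threshold on the z map (default 1.65).
#' @return a \linkS4class{GroupMap}.
#' @export
signFlipGroupMap <- function(diffs, dims, maskIdx, nPerm = 10000L,
                             seed = NULL, E = 0.5, H = 2,
                             nSteps = 100L, zThreshold = 1.65) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  stopifnot(n >= 2L, ncol(diffs) == length(maskIdx))
  if (nPerm < 100L) warning("nPerm < 100: permutation tails unstable")
  nPerm <- as.integer(nPerm)

  tmap <- function(meanV, varV) {
    se <- sqrt(varV / n)
    ifelse(se > 0, meanV / se, 0)
  }
  ssq <- colSums(diffs^2)
  mObs <- colMeans(diffs)
  vObs <- pmax(ssq - n * mObs^2, 0) / (n - 1)
  obs <- tfce(tmap(mObs, vObs), dims, maskIdx, E, H, nSteps)

  signs <- withSeed(seed,
    matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n))
  nullMax <- numeric(nPerm)
  block <- max(1L, min(nPerm, floor(2e7 / max(length(maskIdx), 1L))))
  for (s in seq(1L, nPerm, by = block)) {
    e <- min(s + block - 1L, nPerm)
    mPerm <- (signs[s:e, , drop = FALSE] %*% diffs) / n
    vPerm <- sweep(-n * mPerm^2, 2L, ssq, "+") / (n - 1)
    tPerm <- mPerm / sqrt(pmax(vPerm, 0) / n)
    tPerm[!is.finite(tPerm)] <- 0
    nullMax[s:e] <- .tfceMaxBatchCpp(tPerm, as.integer(dims),
                                     as.integer(maskIdx), E, H,
                                     as.integer(nSteps))
  }

  sortedNull <- sort(nullMax)
  nGE <- nPerm - findInterval(obs - 1e-12, sortedNull)
  p <- (1 + nGE) / (nPerm + 1)
  z <- qnorm(1 - pmin(p, 1 - 1 / (nPerm + 1)))
  new("GroupMap", z = z, p = p, tfceObserved = obs,
      centers = as.integer(maskIdx), dims = as.integer(dims),
      threshold = zThreshold, nPerm = nPerm)
}

#' Suprathreshold voxels of a group map
#'
#' @param map a \linkS4class{GroupMap}.
#' @return integer linear grid indices with z above the map's threshold.
#' @export
suprathresholdVoxels <- function(map) {
  map@centers[map@z > map@threshold]
}
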