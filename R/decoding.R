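DECODED_CATEGORIES <- c("tools", "faces", "places")

comparisonLabel <- function(c1, c2) {
  paste0(toupper(substr(c1, 1, 1)), "v", toupper(substr(c2, 1, 1)))
}

#' Fit the GLM and compute residuals for one subject
#'
#' Convenience wrapper computing the two per-subject products every
#' analysis consumes: run-wise GLM stat maps (task + drift + motion +
#' intercept design) and task-regressed band-passed residual series.
#' Passing the result to the decoding functions avoids recomputing them.
#'
#' @param subject a \linkS4class{SubjectDataset}.
#' @param hpCutoffSeconds high-pass cutoff (default 256 s).
#' @return list with elements \code{statmaps} (per-run
#'   \linkS4class{RunStatMaps}) and \code{residuals} (per-run residual
#'   matrices).
#' @export
prepareSubject <- function(subject, hpCutoffSeconds = 256) {
  statmaps <- lapply(seq_len(nRuns(subject)), function(r) {
    dm <- buildDesignMatrix(subject@design, r,
                            motion = subject@motion[[r]],
                            hpCutoffSeconds = hpCutoffSeconds)
    fitGlmRun(subject@runs[[r]], dm)
  })
  list(statmaps = statmaps,
       residuals = subjectResiduals(subject, hpCutoffSeconds))
}

#' Extract the split condition patterns for one comparison
#'
#' For each decoding split, the condition pattern is the mean of the
#' run-wise condition betas over that split's runs, restricted to the
#' voxel set; both halves share condition and voxel order.
#'
#' @param statmaps list of per-run \linkS4class{RunStatMaps}.
#' @param cols integer column positions of the voxel set in the data
#'   matrices.
#' @param splits list of two run-index vectors (the decoding splits).
#' @param comparison character(2), the two condition names.
#' @return a \linkS4class{PatternPair}.
#' @export
extractPatterns <- function(statmaps, cols, splits, comparison) {
  stopifnot(length(splits) == 2L, length(comparison) == 2L)
  nvox <- ncol(statmaps[[1]]@coef)
  if (anyNA(cols) || any(cols < 1L) || any(cols > nvox))
    stop("voxel set references voxels outside the data")
  half <- function(runs) {
    mats <- lapply(runs, function(r)
      conditionBetas(statmaps[[r]])[comparison, cols, drop = FALSE])
    Reduce(`+`, mats) / length(mats)
  }
  new("PatternPair", splitA = half(splits[[1]]),
      splitB = half(splits[[2]]), conditions = comparison)
}

#' Split-half correlation decoding accuracy
#'
#' Correlates each condition pattern of the first split with each
#' condition pattern of the second split, giving a 2 (split) x 2
#' (category) confusion matrix; accuracy is the mean within-category
#' (on-diagonal) correlation minus the mean between-category
#' (off-diagonal) correlation, so it lies in [-2, 2] and is positive
#' when patterns are category specific.  A zero-variance pattern makes
#' the accuracy undefined (\code{NA}).
#'
#' @param pair a \linkS4class{PatternPair}.
#' @return numeric accuracy, or \code{NA} if undefined.
#' @export
splitHalfAccuracy <- function(pair) {
  A <- pair@splitA
  B <- pair@splitB
  if (ncol(A) < 3L) stop("need at least 3 voxels for a correlation")
  sds <- c(apply(A, 1, sd), apply(B, 1, sd))
  if (any(!is.finite(sds)) || any(sds == 0)) return(NA_real_)
  C <- cor(t(A), t(B))
  mean(diag(C)) - mean(C[row(C) != col(C)])
}

# Vectorised split-half accuracy over many voxel subsets of one region:
# idx is a draws-by-k matrix of voxel positions into the four pattern
# vectors (condition 1/2 of split A/B).
subsetAccuracy <- function(idx, a1, a2, b1, b2) {
  k <- ncol(idx)
  m <- nrow(idx)
  gather <- function(x) matrix(x[idx], m, k)
  A1 <- gather(a1); A2 <- gather(a2); B1 <- gather(b1); B2 <- gather(b2)
  s <- lapply(list(A1, A2, B1, B2), rowSums)
  q <- lapply(list(A1, A2, B1, B2), function(M) rowSums(M^2))
  sdpart <- function(i) sqrt(pmax(k * q[[i]] - s[[i]]^2, 0))
  rcor <- function(X, Y, i, j) {
    num <- k * rowSums(X * Y) - s[[i]] * s[[j]]
    den <- sdpart(i) * sdpart(j)
    ifelse(den > 0, num / den, NA_real_)
  }
  (rcor(A1, B1, 1, 3) + rcor(A2, B2, 2, 4)) / 2 -
    (rcor(A1, B2, 1, 4) + rcor(A2, B1, 2, 3)) / 2
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel temporal mean divided by temporal SD for one run.
#' Zero-SD voxels are returned as \code{Inf} and should be excluded
#' from set means.
#'
#' @param y time-by-voxel matrix (at least 2 time points).
#' @return numeric per-voxel tSNR.
#' @export
tsnr <- function(y) {
  y <- as.matrix(y)
  stopifnot(nrow(y) >= 2L)
  m <- colMeans(y)
  s <- apply(y, 2, sd)
  ifelse(s > 0, m / s, Inf)
}

# selection products for one subject/region/fold: connectivity profile,
# seed columns, and the selection-split t maps per comparison
selectionInputs <- function(subject, prep, region, selRuns, kSeed = 100L) {
  layout <- subject@layout
  cat <- regionCategory(layout, region)
  targetCols <- regionColumns(subject, region)
  seedCols <- lapply(seedRegionsFor(layout, region), function(sr) {
    cols <- regionColumns(subject, sr)
    tsr <- splitTmap(prep$statmaps, selRuns, categoryContrast(cat))[cols]
    vs <- selectTopK(tsr, kSeed, "most", requireDisjoint = FALSE,
                     mode = "most_activated",
                     contrastUsed = paste0(cat, ">others"))
    cols[voxelIndices(vs)]
  })
  Rsel <- do.call(rbind, prep$residuals[selRuns])
  prof <- connectivityProfile(Rsel[, targetCols, drop = FALSE],
                              lapply(seedCols, function(sc)
                                Rsel[, sc, drop = FALSE]))
  list(category = cat, targetCols = targetCols, profile = prof)
}

#' Decode one subject across regions, folds, comparisons and modes
#'
#' Runs the full within-subject analysis: per fold, voxel sets are
#' defined from the selection split (most/least connected by mean
#' Fisher z to the same-category seed voxels; most activated by the
#' comparison-specific contrast t), and split-half decoding is scored on
#' the two left-out splits.
#'
#' @param subject a \linkS4class{SubjectDataset}.
#' @param scheme a \linkS4class{SplitScheme}.
#' @param k voxel-set size (default 100).
#' @param kSeed seed voxels per seed region (default 100).
#' @param modes selection modes to score.
#' @param prep optional precomputed \code{\link{prepareSubject}} result.
#' @param subjectId label for the output rows.
#' @return list with data frames \code{decoding} (subject, region,
#'   category, comparison, mode, fold, accuracy), \code{connectivity}
#'   (median voxel-set mean-z per set) and \code{snr} (mean voxel-set
#'   tSNR per set).
#' @export
decodeSubject <- function(subject, scheme = makeSplitScheme(),
                          k = 100L, kSeed = 100L,
                          modes = c("most_connected", "least_connected",
                                    "most_activated"),
                          prep = NULL, subjectId = 1L) {
  if (is.null(prep)) prep <- prepareSubject(subject)
  layout <- subject@layout
  snrMap <- rowMeans(vapply(subject@runs, tsnr,
                            numeric(length(subject@voxels))))
  dec <- list(); conn <- list(); snr <- list()

  for (region in targetRegions(layout)) {
    for (f in seq_along(scheme@folds)) {
      fold <- scheme@folds[[f]]
      si <- selectionInputs(subject, prep, region, fold$selection, kSeed)
      others <- setdiff(DECODED_CATEGORIES, si$category)
      prof <- si$profile

      sets <- list()
      if ("most_connected" %in% modes)
        sets$most_connected <- selectTopK(meanZ(prof), k, "most",
                                          eligible = prof@eligible,
                                          foldId = f)
      if ("least_connected" %in% modes)
        sets$least_connected <- selectTopK(meanZ(prof), k, "least",
                                           eligible = prof@eligible,
                                           foldId = f)

      for (setMode in names(sets)) {
        loc <- voxelIndices(sets[[setMode]])
        conn[[length(conn) + 1L]] <- data.frame(
          subject = subjectId, region = region, category = si$category,
          mode = setMode, fold = f,
          medianZ = median(meanZ(prof)[loc]))
        v <- snrMap[si$targetCols[loc]]
        snr[[length(snr) + 1L]] <- data.frame(
          subject = subjectId, region = region, category = si$category,
          mode = setMode, fold = f, tsnr = mean(v[is.finite(v)]))
      }

      for (other in others) {
        comparison <- c(si$category, other)
        cmpLab <- comparisonLabel(si$category, other)
        cmpSets <- sets
        if ("most_activated" %in% modes) {
          tpair <- splitTmap(prep$statmaps, fold$selection,
                             pairContrast(si$category,
                                          other))[si$targetCols]
          cmpSets$most_activated <- selectMostActivated(
            tpair, k, contrast = cmpLab,
            eligible = is.finite(tpair) & prof@eligible, foldId = f)
        }
        for (setMode in names(cmpSets)) {
          cols <- si$targetCols[voxelIndices(cmpSets[[setMode]])]
          pp <- extractPatterns(prep$statmaps, cols, fold$decoding,
                                comparison)
          dec[[length(dec) + 1L]] <- data.frame(
            subject = subjectId, region = region,
            category = si$category, comparison = cmpLab,
            mode = setMode, fold = f,
            accuracy = splitHalfAccuracy(pp))
        }
      }
    }
  }
  list(decoding = do.call(rbind, dec),
       connectivity = do.call(rbind, conn),
       snr = do.call(rbind, snr))
}

#' Decode a whole cohort
#'
#' Applies \code{\link{decodeSubject}} to every subject and binds the
#' long-format decoding table; rows with undefined accuracy are dropped
#' with a message.  Fold accuracies are averaged downstream (see
#' \code{\link{foldAverage}}) before group inference.
#'
#' @param cohort list of \linkS4class{SubjectDataset}.
#' @param scheme a \linkS4class{SplitScheme}.
#' @param extras return the connectivity and tSNR set summaries as well.
#' @inheritParams decodeSubject
#' @return the decoding data frame, or (with \code{extras = TRUE}) a
#'   list of the three tables.
#' @export
decodeAll <- function(cohort, scheme = makeSplitScheme(), k = 100L,
                      kSeed = 100L,
                      modes = c("most_connected", "least_connected",
                                "most_activated"),
                      extras = FALSE) {
  res <- lapply(seq_along(cohort), function(i)
    decodeSubject(cohort[[i]], scheme, k, kSeed, modes,
                  subjectId = i))
  dec <- do.call(rbind, lapply(res, `[[`, "decoding"))
  if (anyNA(dec$accuracy)) {
    message("dropping ", sum(is.na(dec$accuracy)),
            " rows with undefined accuracy")
    dec <- dec[!is.na(dec$accuracy), ]
  }
  if (!extras) return(dec)
  list(decoding = dec,
       connectivity = do.call(rbind, lapply(res, `[[`, "connectivity")),
       snr = do.call(rbind, lapply(res, `[[`, "snr")))
}

#' Average decoding accuracy across folds
#'
#' @param table a decoding data frame from \code{\link{decodeAll}}.
#' @return data frame with one row per subject, region, comparison and
#'   mode, with \code{accuracy} averaged over folds.
#' @export
foldAverage <- function(table) {
  aggregate(accuracy ~ subject + region + category + comparison + mode,
            data = table, FUN = mean)
}

#' Activation-matched decoding for one subject
#'
#' Runs the matched-activation permutation per region, comparison and
#' fold: voxels are median-split by mean connectivity, random k-subset
#' pairs are drawn from the two halves, pairs whose mean activation
#' differs under the threshold mode are discarded, and decoding accuracy
#' is averaged over the retained pairs to give stable strongly connected
#' and weakly connected estimates.
#'
#' @inheritParams decodeSubject
#' @param thresholdMode matching constraint: \code{"liberal"},
#'   \code{"intermediate"} or \code{"strict"}.
#' @param nDraws subset comparisons per analysis (default 10000).
#' @param seed RNG seed for the draws (independent of the simulation
#'   stream).
#' @return data frame with columns subject, region, category,
#'   comparison, mode (\code{matched_strong}/\code{matched_weak}), fold,
#'   accuracy, nRetained and retention; accuracy is \code{NA} when no
#'   pair satisfied the constraint.
#' @export
matchedDecodeSubject <- function(subject, scheme = makeSplitScheme(),
                                 thresholdMode = "liberal", k = 100L,
                                 kSeed = 100L, nDraws = 10000L,
                                 seed = NULL, prep = NULL,
                                 subjectId = 1L) {
  if (is.null(prep)) prep <- prepareSubject(subject)
  layout <- subject@layout
  seeds <- childSeeds(if (is.null(seed)) 0L else seed,
                      length(targetRegions(layout)) *
                        length(scheme@folds) * 2L)
  si <- 0L
  out <- list()
  for (region in targetRegions(layout)) {
    for (f in seq_along(scheme@folds)) {
      fold <- scheme@folds[[f]]
      sel <- selectionInputs(subject, prep, region, fold$selection, kSeed)
      others <- setdiff(DECODED_CATEGORIES, sel$category)
      for (other in others) {
        si <- si + 1L
        comparison <- c(sel$category, other)
        cmpLab <- comparisonLabel(sel$category, other)
        tpair <- splitTmap(prep$statmaps, fold$selection,
                           pairContrast(sel$category,
                                        other))[sel$targetCols]
        mp <- matchedActivationPairs(
          meanZ(sel$profile), tpair, k, thresholdMode, nDraws,
          seed = seeds[si],
          eligible = sel$profile@eligible & is.finite(tpair),
          foldId = f, contrastUsed = cmpLab)

        accS <- accW <- NA_real_
        if (nRetained(mp) > 0L) {
          betas <- lapply(fold$decoding, function(runs) {
            mats <- lapply(runs, function(r)
              conditionBetas(prep$statmaps[[r]])[comparison,
                                                 sel$targetCols,
                                                 drop = FALSE])
            Reduce(`+`, mats) / length(mats)
          })
          acc <- function(idx)
            mean(subsetAccuracy(idx, betas[[1]][1, ], betas[[1]][2, ],
                                betas[[2]][1, ], betas[[2]][2, ]),
                 na.rm = TRUE)
          accS <- acc(mp@strong)
          accW <- acc(mp@weak)
        }
        out[[length(out) + 1L]] <- data.frame(
          subject = subjectId, region = region, category = sel$category,
          comparison = cmpLab,
          mode = c("matched_strong", "matched_weak"), fold = f,
          accuracy = c(accS, accW), nRetained = nRetained(mp),
          retention = retentionRate(mp))
      }
    }
  }
  do.call(rbind, out)
}

#' Activation-matched decoding for a cohort
#'
#' @inheritParams decodeAll
#' @param thresholdMode matching constraint (see
#'   \code{\link{matchedDecodeSubject}}).
#' @param nDraws subset comparisons per analysis.
#' @param seed master RNG seed for all subjects' draws.
#' @return combined matched-decoding data frame.
#' @export
matchedDecodeAll <- function(cohort, scheme = makeSplitScheme(),
                             thresholdMode = "liberal", k = 100L,
                             kSeed = 100L, nDraws = 10000L, seed = 1L) {
  seeds <- childSeeds(seed, length(cohort))
  do.call(rbind, lapply(seq_along(cohort), function(i)
    matchedDecodeSubject(cohort[[i]], scheme, thresholdMode, k, kSeed,
                         nDraws, seed = seeds[i], subjectId = i)))
}
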