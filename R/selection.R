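#' Build the leave-one-split-out scheme
#'
#' Partitions the six runs into three splits of two runs each and
#' defines three folds; in each fold one split supplies the selection
#' data (connectivity scores, activation t values) and the remaining two
#' splits supply the decoding data, keeping selection and decoding data
#' disjoint.
#'
#' @param nRuns number of runs; must be 6 unless \code{splits} overrides
#'   the partition explicitly.
#' @param seed RNG seed for randomizing which runs are paired; with
#'   \code{seed = NULL} the chronological pairing (1,2), (3,4), (5,6)
#'   is used.
#' @param splits optional explicit partition: a list of run-index
#'   vectors.
#' @return a \linkS4class{SplitScheme}.
#' @export
makeSplitScheme <- function(nRuns = 6L, seed = NULL, splits = NULL) {
  if (is.null(splits)) {
    if (nRuns != 6L)
      stop("the default scheme requires 6 runs; pass an explicit ",
           "'splits' partition otherwise")
    perm <- if (is.null(seed)) seq_len(6L) else withSeed(seed, sample(6L))
    splits <- list(perm[1:2], perm[3:4], perm[5:6])
  }
  if (!setequal(unlist(splits), seq_len(nRuns)) ||
      length(unlist(splits)) != nRuns)
    stop("splits must partition the runs")
  splits <- lapply(splits, function(s) sort(as.integer(s)))
  folds <- lapply(seq_along(splits), function(i)
    list(selection = splits[[i]], decoding = splits[-i]))
  new("SplitScheme", splits = splits, folds = folds)
}

#' Select the k highest- or lowest-scoring voxels
#'
#' Returns the k eligible voxels with the largest (\code{"most"}) or
#' smallest (\code{"least"}) scores; ties are broken by ascending voxel
#' index.  When at least 2k voxels are eligible the most and least sets
#' of the same scores are disjoint by construction; by default fewer
#' than 2k eligible voxels is an error so that this disjointness
#' contract always holds (pass \code{requireDisjoint = FALSE} to select
#' from smaller pools).
#'
#' @param scores numeric selection scores (e.g. mean Fisher z).
#' @param k set size (default 100).
#' @param direction \code{"most"} or \code{"least"}.
#' @param eligible logical eligibility mask; defaults to finite scores.
#' @param requireDisjoint error when fewer than 2k voxels are eligible
#'   (default TRUE).
#' @param foldId integer fold label.
#' @param mode selection-mode label stored on the result; defaults to
#'   \code{most_connected}/\code{least_connected} by direction.
#' @param contrastUsed contrast label for activation-based selection.
#' @return a \linkS4class{VoxelSet} (indices ordered by score rank).
#' @export
selectTopK <- function(scores, k = 100L, direction = c("most", "least"),
                       eligible = NULL, requireDisjoint = TRUE,
                       foldId = NA_integer_, mode = NULL,
                       contrastUsed = NA_character_) {
  direction <- match.arg(direction)
  k <- as.integer(k)
  if (is.null(eligible)) eligible <- is.finite(scores)
  ids <- which(eligible)
  if (requireDisjoint && length(ids) < 2L * k)
    stop("need at least 2k = ", 2L * k, " eligible voxels, have ",
         length(ids))
  if (length(ids) < k)
    stop("need at least k = ", k, " eligible voxels, have ", length(ids))
  s <- scores[ids]
  ord <- if (direction == "most") order(-s, ids) else order(s, ids)
  if (is.null(mode))
    mode <- if (direction == "most") "most_connected" else
      "least_connected"
  new("VoxelSet", indices = ids[ord[seq_len(k)]], k = k, mode = mode,
      foldId = as.integer(foldId), contrastUsed = contrastUsed)
}

#' Select the k most-activated voxels
#'
#' Top-k voxels by the contrast t values of the selection split, with
#' the contrast matched to the decoding comparison (e.g. tools > faces t
#' values for tools-versus-faces decoding).  Overlap with
#' connectivity-selected sets is unconstrained.
#'
#' @param tmap per-voxel contrast t values (selection split only).
#' @param k set size (default 100).
#' @param contrast contrast label recorded on the set.
#' @param eligible logical eligibility mask; defaults to finite t.
#' @param foldId integer fold label.
#' @param requireDisjoint see \code{\link{selectTopK}}.
#' @return a \linkS4class{VoxelSet} with mode \code{most_activated}.
#' @export
selectMostActivated <- function(tmap, k = 100L,
                                contrast = NA_character_,
                                eligible = NULL, foldId = NA_integer_,
                                requireDisjoint = TRUE) {
  selectTopK(tmap, k, "most", eligible = eligible,
             requireDisjoint = requireDisjoint, foldId = foldId,
             mode = "most_activated", contrastUsed = contrast)
}

#' Activation-matched strongly/weakly connected voxel-set pairs
#'
#' Median-splits the eligible voxels by their mean connectivity score,
#' then repeatedly draws one random k-subset from each half and retains
#' the pair only if the two subsets' mean activation (t values) does not
#' differ under the chosen constraint, assessed with a pooled-variance
#' two-sample t statistic: \code{liberal} keeps two-tailed p > 0.10,
#' \code{intermediate} keeps t in [-0.5, 0.5], and \code{strict} keeps t
#' in [-0.5, 0] (the strongly connected set's mean activation must not
#' exceed the weak set's).  A degenerate draw with zero pooled variance
#' is defined as t = 0 and passes.  An empty result signals that the
#' constraint could not be met; downstream analyses drop that
#' subject/region.
#'
#' @param meanZ per-voxel mean connectivity score (selection split).
#' @param tValues per-voxel activation t values (selection split,
#'   comparison-specific contrast).
#' @param k subset size (default 100).
#' @param thresholdMode \code{"liberal"}, \code{"intermediate"} or
#'   \code{"strict"}.
#' @param nDraws number of subset comparisons (default 10000).
#' @param seed RNG seed for the draws (independent of any simulation
#'   stream).
#' @param eligible logical mask; defaults to voxels with finite scores
#'   and finite t values.
#' @param foldId integer fold label.
#' @param contrastUsed contrast label recorded on the result.
#' @return a \linkS4class{MatchedPairSet} (possibly with zero retained
#'   pairs).
#' @export
matchedActivationPairs <- function(meanZ, tValues, k = 100L,
                                   thresholdMode = c("liberal",
                                                     "intermediate",
                                                     "strict"),
                                   nDraws = 10000L, seed = NULL,
                                   eligible = NULL,
                                   foldId = NA_integer_,
                                   contrastUsed = NA_character_) {
  thresholdMode <- match.arg(thresholdMode)
  k <- as.integer(k)
  if (is.null(eligible)) eligible <- is.finite(meanZ) & is.finite(tValues)
  ids <- which(eligible)
  n <- length(ids)
  half <- n %/% 2L
  empty <- function() new("MatchedPairSet",
                          strong = matrix(integer(), 0L, k),
                          weak = matrix(integer(), 0L, k),
                          tStat = numeric(), mode = thresholdMode,
                          k = k, nDraws = as.integer(nDraws),
                          foldId = as.integer(foldId),
                          contrastUsed = contrastUsed)
  if (half < k) return(empty())
  ord <- ids[order(meanZ[ids], ids)]
  lowHalf <- ord[seq_len(half)]
  highHalf <- ord[(n - half + 1L):n]

  dr <- withSeed(seed,
                 .matchedDrawsCpp(highHalf, lowHalf, tValues, k,
                                  as.integer(nDraws)))
  keep <- switch(thresholdMode,
    liberal = 2 * pt(-abs(dr$tstat), df = 2L * k - 2L) > 0.10,
    intermediate = dr$tstat >= -0.5 & dr$tstat <= 0.5,
    strict = dr$tstat >= -0.5 & dr$tstat <= 0
  )
  new("MatchedPairSet",
      strong = dr$strong[keep, , drop = FALSE],
      weak = dr$weak[keep, , drop = FALSE],
      tStat = dr$tstat[keep], mode = thresholdMode, k = k,
      nDraws = as.integer(nDraws), foldId = as.integer(foldId),
      contrastUsed = contrastUsed)
}

#' Serialize voxel sets to JSON
#'
#' Writes a list of \linkS4class{VoxelSet}s as a JSON array of records
#' (indices, k, mode, fold, contrast), the interchange format for
#' selected sets.
#'
#' @param sets a \linkS4class{VoxelSet} or list of them.
#' @param file output path; with \code{NULL} the JSON string is
#'   returned.
#' @return the file path (invisibly) or the JSON string.
#' @export
writeVoxelSetJson <- function(sets, file = NULL) {
  if (is(sets, "VoxelSet")) sets <- list(sets)
  rec <- lapply(sets, function(v) list(
    indices = voxelIndices(v), k = v@k, mode = v@mode,
    fold = v@foldId, contrast = v@contrastUsed))
  if (is.null(file))
    return(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(rec, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read voxel sets serialized with \code{\link{writeVoxelSetJson}}
#'
#' @param file path to the JSON file.
#' @return list of \linkS4class{VoxelSet}.
#' @export
readVoxelSetJson <- function(file) {
  rec <- jsonlite::read_json(file, simplifyVector = FALSE)
  lapply(rec, function(r) new(
    "VoxelSet", indices = as.integer(unlist(r$indices)),
    k = as.integer(r$k), mode = r$mode,
    foldId = as.integer(if (is.null(r$fold)) NA else r$fold),
    contrastUsed = as.character(if (is.null(r$contrast)) NA
                                else r$contrast)))
}
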