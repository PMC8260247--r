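#' @import methods
#' @importFrom stats rnorm runif cor sd var qnorm pnorm pt qt dgamma
#'   aggregate as.formula aov complete.cases fft mvfft median quantile
#'   setNames convolve
#' @importFrom utils head write.csv read.csv
NULL

#' Spatial layout of target, seed and tissue voxels on a 3-D grid
#'
#' A \code{RegionLayout} fixes the geometry every other stage works on: an
#' isotropic voxel grid (unit spacing, no physical mm), a set of named
#' regions given as integer voxel coordinates, a role (\code{"target"} or
#' \code{"seed"}) and a stimulus category for each region, a gray-matter
#' mask of voxels eligible for analysis, and a set of non-gray
#' ("white-matter") voxels used only to form the global-signal nuisance
#' proxy.
#'
#' @slot gridDims integer(3), voxels per axis.
#' @slot regions named list of integer matrices (one row per voxel, columns
#'   x/y/z).
#' @slot roles named character, \code{"target"} or \code{"seed"} per region.
#' @slot categories named character, stimulus category per region.
#' @slot gray integer matrix of gray-matter voxel coordinates.
#' @slot white integer matrix of non-gray voxel coordinates.
#' @export
setClass("RegionLayout",
  representation(
    gridDims = "integer",
    regions = "list",
    roles = "character",
    categories = "character",
    gray = "matrix",
    white = "matrix"
  )
)

setValidity("RegionLayout", function(object) {
  msg <- character()
  if (length(object@gridDims) != 3L || any(object@gridDims < 1L))
    msg <- c(msg, "gridDims must be three positive integers")
  nm <- names(object@regions)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    msg <- c(msg, "regions must be uniquely named")
  if (!setequal(names(object@roles), nm) ||
      !setequal(names(object@categories), nm))
    msg <- c(msg, "roles and categories must name every region")
  if (!all(object@roles %in% c("target", "seed")))
    msg <- c(msg, "roles must be 'target' or 'seed'")
  for (r in nm) {
    co <- object@regions[[r]]
    if (any(co < 1L) || any(t(co) > object@gridDims))
      msg <- c(msg, sprintf("region '%s' exceeds the grid", r))
  }
  if (length(msg)) msg else TRUE
})

#' Effect specification for the synthetic-cohort generator
#'
#' Collects every knob of the generative model: how strongly informative
#' target voxels and seed voxels share a latent band-limited signal
#' (\code{couplingStrength}, the SD ratio of the shared to the private
#' noise component), which fraction of target voxels is informative,
#' the amplitude of category-specific multivoxel patterns relative to the
#' noise SD (\code{patternSnr}), the univariate activation amplitude
#' (\code{activationGain}, dissociable from connectivity by construction),
#' the noise SD and baseline in arbitrary BOLD units, and the RNG seed.
#'
#' @export
setClass("EffectSpec",
  representation(
    couplingStrength = "numeric",
    fracInformative = "numeric",
    patternSnr = "numeric",
    activationGain = "numeric",
    noiseSd = "numeric",
    baseline = "numeric",
    seed = "integer"
  )
)

setValidity("EffectSpec", function(object) {
  msg <- character()
  for (s in c("couplingStrength", "fracInformative", "patternSnr",
              "activationGain", "noiseSd", "baseline")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single nonnegative number", s))
  }
  if (object@fracInformative > 1)
    msg <- c(msg, "fracInformative must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Block-design specification
#'
#' Onsets, durations and condition labels for every run of the blocked
#' design, plus the repetition time and run length in volumes.
#'
#' @slot trSeconds repetition time in seconds.
#' @slot nVolumes volumes per run.
#' @slot runs list of data frames with columns \code{condition},
#'   \code{onset} (s) and \code{duration} (s).
#' @slot conditions character, the full condition set in canonical order.
#' @export
setClass("DesignSpec",
  representation(
    trSeconds = "numeric",
    nVolumes = "integer",
    runs = "list",
    conditions = "character"
  )
)

setValidity("DesignSpec", function(object) {
  msg <- character()
  for (ev in object@runs) {
    if (!all(c("condition", "onset", "duration") %in% names(ev)))
      msg <- c(msg, "each run needs condition/onset/duration columns")
    else {
      if (!all(ev$condition %in% object@conditions))
        msg <- c(msg, "unknown condition label in a run")
      if (any(ev$onset + ev$duration >
              object@nVolumes * object@trSeconds + 1e-9))
        msg <- c(msg, "a block extends past the end of the run")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject synthetic dataset
#'
#' Multi-run voxel time series on a \linkS4class{RegionLayout}, with the
#' design, simulated head-motion series and a ground-truth record.  The
#' truth slot (planted informative-voxel indices, pattern vectors, gains)
#' is written by the simulator and read only by tests; no analysis stage
#' touches it.
#'
#' @slot runs list of time-by-voxel matrices (BOLD arbitrary units).
#' @slot voxels integer linear grid indices labelling the columns of each
#'   run matrix.
#' @slot trSeconds repetition time in seconds.
#' @slot layout a \linkS4class{RegionLayout}.
#' @slot design a \linkS4class{DesignSpec}.
#' @slot motion list of time-by-6 simulated rigid-motion series.
#' @slot truth list; ground truth for tests only.
#' @export
setClass("SubjectDataset",
  representation(
    runs = "list",
    voxels = "integer",
    trSeconds = "numeric",
    layout = "RegionLayout",
    design = "DesignSpec",
    motion = "list",
    truth = "list"
  )
)

setValidity("SubjectDataset", function(object) {
  msg <- character()
  nv <- vapply(object@runs, ncol, 1L)
  if (length(unique(nv)) > 1L)
    msg <- c(msg, "all runs must share one voxel count")
  if (length(nv) && nv[1] != length(object@voxels))
    msg <- c(msg, "voxel index length must match run columns")
  if (length(object@motion) &&
      length(object@motion) != length(object@runs))
    msg <- c(msg, "one motion matrix per run required")
  if (length(msg)) msg else TRUE
})

#' First-level design matrix
#'
#' Time-by-regressor matrix holding one HRF-convolved regressor per
#' condition, discrete-cosine drift terms implementing the high-pass
#' cutoff, six rigid-motion regressors when supplied, and exactly one
#' intercept.
#'
#' @slot matrix numeric time-by-regressor matrix with column names.
#' @slot conditionNames character, names of the condition columns.
#' @slot trSeconds repetition time in seconds.
#' @export
setClass("DesignMatrix",
  representation(
    matrix = "matrix",
    conditionNames = "character",
    trSeconds = "numeric"
  )
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  cn <- colnames(object@matrix)
  if (is.null(cn)) msg <- c(msg, "design matrix must have column names")
  else {
    if (sum(cn == "intercept") != 1L)
      msg <- c(msg, "exactly one intercept column required")
    if (!all(object@conditionNames %in% cn))
      msg <- c(msg, "condition columns missing from matrix")
  }
  if (length(msg)) msg else TRUE
})

#' Run-wise GLM estimates
#'
#' OLS coefficient maps, residual variance and degrees of freedom for one
#' run, from which contrast t maps are derived.
#'
#' @slot coef regressor-by-voxel coefficient matrix.
#' @slot conditionNames character, which rows are condition betas.
#' @slot residualDf integer residual degrees of freedom.
#' @slot residualVariance per-voxel residual variance.
#' @slot xtxInv inverse of the design Gram matrix.
#' @export
setClass("RunStatMaps",
  representation(
    coef = "matrix",
    conditionNames = "character",
    residualDf = "integer",
    residualVariance = "numeric",
    xtxInv = "matrix"
  )
)

#' Voxelwise functional-connectivity profile
#'
#' Fisher-z correlation of every target-region voxel with every
#' same-category seed voxel, plus the per-voxel mean across all seed
#' voxels used as the selection score.
#'
#' @slot zMatrix target-voxel by seed-voxel Fisher-z matrix.
#' @slot meanZ per-target-voxel mean Fisher z across all seed voxels.
#' @slot foldId integer fold the selection split belongs to.
#' @slot eligible logical, FALSE for zero-variance (flagged) voxels.
#' @export
setClass("ConnectivityProfile",
  representation(
    zMatrix = "matrix",
    meanZ = "numeric",
    foldId = "integer",
    eligible = "logical"
  )
)

setValidity("ConnectivityProfile", function(object) {
  msg <- character()
  if (length(object@meanZ) != nrow(object@zMatrix))
    msg <- c(msg, "meanZ length must equal target voxel count")
  if (length(object@eligible) != length(object@meanZ))
    msg <- c(msg, "eligible length must equal target voxel count")
  if (any(!is.finite(object@zMatrix[object@eligible, , drop = FALSE])))
    msg <- c(msg, "z values of eligible voxels must be finite")
  if (length(msg)) msg else TRUE
})

#' Leave-one-split-out scheme over runs
#'
#' Partitions the runs into three splits of two and defines one fold per
#' split: the split supplies the selection data and the remaining two
#' splits supply the decoding data.
#'
#' @slot splits list of three integer pairs partitioning the runs.
#' @slot folds list; per fold, \code{selection} (run indices) and
#'   \code{decoding} (list of two run-index pairs).
#' @export
setClass("SplitScheme",
  representation(splits = "list", folds = "list")
)

setValidity("SplitScheme", function(object) {
  msg <- character()
  all_runs <- sort(unlist(object@splits))
  if (any(duplicated(all_runs)))
    msg <- c(msg, "splits must be disjoint")
  sel <- vapply(object@folds, function(f) paste(sort(f$selection),
                                                collapse = ","), "")
  spl <- vapply(object@splits, function(s) paste(sort(s), collapse = ","), "")
  if (!setequal(sel, spl) || anyDuplicated(sel))
    msg <- c(msg, "each split must be the selection split of exactly one fold")
  if (length(msg)) msg else TRUE
})

#' An ordered set of selected voxels
#'
#' @slot indices ordered integer voxel indices (positions within the score
#'   vector or region the set was selected from).
#' @slot k set size.
#' @slot mode selection mode, one of \code{most_connected},
#'   \code{least_connected}, \code{most_activated}, \code{matched_strong},
#'   \code{matched_weak}.
#' @slot foldId integer fold of the selection split.
#' @slot contrastUsed contrast label for activation-based modes.
#' @export
setClass("VoxelSet",
  representation(
    indices = "integer",
    k = "integer",
    mode = "character",
    foldId = "integer",
    contrastUsed = "character"
  )
)

setValidity("VoxelSet", function(object) {
  msg <- character()
  if (length(object@indices) != object@k)
    msg <- c(msg, "indices length must equal k")
  if (anyDuplicated(object@indices))
    msg <- c(msg, "indices must be unique")
  modes <- c("most_connected", "least_connected", "most_activated",
             "matched_strong", "matched_weak")
  if (!object@mode %in% modes)
    msg <- c(msg, "unknown selection mode")
  if (length(msg)) msg else TRUE
})

#' Retained activation-matched voxel-set pairs
#'
#' Result of the matched-activation permutation: all retained draws of one
#' strongly connected and one weakly connected k-subset whose mean
#' activation t values satisfy the threshold mode.  Index matrices are
#' stored row-per-pair for vectorised downstream decoding;
#' \code{\link{pairVoxelSets}} materialises a single pair as two
#' \linkS4class{VoxelSet}s.
#'
#' @slot strong retained-by-k index matrix, strongly connected subsets.
#' @slot weak retained-by-k index matrix, weakly connected subsets.
#' @slot tStat matching two-sample t statistic per retained pair.
#' @slot mode threshold mode: liberal, intermediate or strict.
#' @slot k subset size.
#' @slot nDraws number of draws performed.
#' @slot foldId integer fold id.
#' @slot contrastUsed activation contrast used for matching.
#' @export
setClass("MatchedPairSet",
  representation(
    strong = "matrix",
    weak = "matrix",
    tStat = "numeric",
    mode = "character",
    k = "integer",
    nDraws = "integer",
    foldId = "integer",
    contrastUsed = "character"
  )
)

#' Pair of split condition patterns for one binary comparison
#'
#' @slot splitA 2-by-k matrix of run-averaged condition betas, first split.
#' @slot splitB same for the second split; identical condition and voxel
#'   order.
#' @slot conditions the two condition labels (row order of both halves).
#' @export
setClass("PatternPair",
  representation(
    splitA = "matrix",
    splitB = "matrix",
    conditions = "character"
  )
)

setValidity("PatternPair", function(object) {
  msg <- character()
  if (!identical(dim(object@splitA), dim(object@splitB)))
    msg <- c(msg, "split halves must share dimensions")
  if (nrow(object@splitA) != 2L)
    msg <- c(msg, "a pattern pair holds exactly two conditions")
  if (length(msg)) msg else TRUE
})

#' Good-seed searchlight maps for one subject
#'
#' Per-center decoding accuracy when the searchlight neighborhood's mean
#' residual time course supplies the connectivity criterion, for the
#' most-connected and least-connected target voxel sets.
#'
#' @slot centers integer linear grid indices of searchlight centers.
#' @slot most accuracy per center, most-connected selection.
#' @slot least accuracy per center, least-connected selection.
#' @slot dims integer(3) grid dimensions.
#' @slot targetRegion region name.
#' @slot comparison the two decoded conditions.
#' @export
setClass("SearchlightMap",
  representation(
    centers = "integer",
    most = "numeric",
    least = "numeric",
    dims = "integer",
    targetRegion = "character",
    comparison = "character"
  )
)

setValidity("SearchlightMap", function(object) {
  if (length(object@most) != length(object@centers) ||
      length(object@least) != length(object@centers))
    "value count must equal center count" else TRUE
})

#' Group-level permutation map
#'
#' Per-voxel z scores from the max-statistic sign-flip permutation null of
#' the TFCE-enhanced group t map, with the survival threshold applied.
#'
#' @slot z per-voxel z score (from FWE-corrected permutation p).
#' @slot p per-voxel FWE-corrected permutation p value.
#' @slot tfceObserved observed TFCE-enhanced statistic per voxel.
#' @slot centers integer linear grid indices the values live on.
#' @slot dims integer(3) grid dimensions.
#' @slot threshold z threshold defining the suprathreshold mask.
#' @slot nPerm number of permutations.
#' @export
setClass("GroupMap",
  representation(
    z = "numeric",
    p = "numeric",
    tfceObserved = "numeric",
    centers = "integer",
    dims = "integer",
    threshold = "numeric",
    nPerm = "integer"
  )
)
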