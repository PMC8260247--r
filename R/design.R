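INTACT_CONDITIONS <- c("tools", "faces", "places", "animals")
ALL_CONDITIONS <- c(INTACT_CONDITIONS, paste0("scrambled_", INTACT_CONDITIONS))

# Evaluate expr under a temporary RNG state; the caller's stream is
# untouched. seed = NULL runs expr with the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Spawn n reproducible child seeds from one master seed (kept below 2^31).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Construct the blocked task design
#'
#' Builds the event tables of the blocked design: per run, two 6 s blocks
#' for each intact category (tools, faces, places, animals) and one 6 s
#' block for each phase-scrambled variant, every block followed by 6 s of
#' fixation, with 16 s fixation prepended and appended.  Block order is
#' randomized independently per run.  With the defaults each run lasts
#' 176 s, i.e. 88 volumes at TR = 2 s.
#'
#' @param nRuns number of runs (default 6).
#' @param seed RNG seed controlling the block orders; the same seed
#'   always yields the same design.
#' @param trSeconds repetition time in seconds (default 2).
#' @param blockSeconds stimulus block duration (default 6).
#' @param fixationSeconds fixation after each block (default 6).
#' @param leadSeconds fixation at the start and end of each run
#'   (default 16).
#' @return a \linkS4class{DesignSpec}.
#' @examples
#' d <- makeDesign(6, seed = 1)
#' d@nVolumes  # 88
#' @export
makeDesign <- function(nRuns = 6L, seed = NULL, trSeconds = 2,
                       blockSeconds = 6, fixationSeconds = 6,
                       leadSeconds = 16) {
  stopifnot(nRuns >= 1L)
  labels <- c(rep(INTACT_CONDITIONS, each = 2L),
              paste0("scrambled_", INTACT_CONDITIONS))
  cycle <- blockSeconds + fixationSeconds
  total <- 2 * leadSeconds + length(labels) * cycle
  if (abs(total / trSeconds - round(total / trSeconds)) > 1e-9)
    stop("run length is not a whole number of volumes at this TR")
  nVol <- as.integer(round(total / trSeconds))

  runs <- withSeed(seed, lapply(seq_len(nRuns), function(r) {
    ord <- sample(labels)
    data.frame(condition = ord,
               onset = leadSeconds + (seq_along(ord) - 1L) * cycle,
               duration = blockSeconds,
               stringsAsFactors = FALSE)
  }))

  new("DesignSpec", trSeconds = trSeconds, nVolumes = nVol,
      runs = runs, conditions = ALL_CONDITIONS)
}

#' Construct an effect specification
#'
#' Returns an \linkS4class{EffectSpec} with the package's default
#' generative conditions.  \code{couplingStrength} is the SD ratio of
#' the shared band-limited latent signal to the private noise in coupled
#' voxels (the total non-task variance is held at \code{noiseSd^2}
#' regardless, so coupling does not alter voxel variance or activation t
#' values); \code{patternSnr} scales the category-specific multivoxel
#' patterns in noise-SD units; \code{activationGain} scales the
#' univariate preferred-category response independently of coupling.
#'
#' @param couplingStrength shared-to-private SD ratio of the latent
#'   signal in coupled voxels (default 0.5).
#' @param fracInformative fraction of target voxels carrying the latent
#'   signal and the category patterns (default 0.5).
#' @param patternSnr amplitude of category-specific patterns relative to
#'   noise SD (default 0.3).
#' @param activationGain univariate preferred-category amplitude in
#'   noise-SD units (default 1).
#' @param noiseSd noise standard deviation, BOLD arbitrary units
#'   (default 1).
#' @param baseline mean signal level, BOLD arbitrary units (default 100).
#' @param seed integer RNG seed (default 1).
#' @return an \linkS4class{EffectSpec}.
#' @export
effectSpec <- function(couplingStrength = 0.5, fracInformative = 0.5,
                       patternSnr = 0.3, activationGain = 1,
                       noiseSd = 1, baseline = 100, seed = 1L) {
  new("EffectSpec", couplingStrength = couplingStrength,
      fracInformative = fracInformative, patternSnr = patternSnr,
      activationGain = activationGain, noiseSd = noiseSd,
      baseline = baseline, seed = as.integer(seed))
}

#' The null effect specification
#'
#' Convenience wrapper: no coupling, no patterns, no activation — pure
#' baseline-plus-noise data for calibration studies.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed to \code{\link{effectSpec}}.
#' @return an \linkS4class{EffectSpec}.
#' @export
nullEffectSpec <- function(seed = 1L, ...) {
  args <- list(couplingStrength = 0, patternSnr = 0, activationGain = 0,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(effectSpec, args)
}
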