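#' Band-limited Gaussian series
#'
#' Unit-SD Gaussian noise restricted to a frequency band by Fourier
#' masking; used for the shared latent coupling signal so that planted
#' connectivity lies inside the band the analysis pipeline retains.
#'
#' @param n number of samples.
#' @param trSeconds sampling interval.
#' @param lowHz,highHz band edges (defaults 0.01 and 0.1 Hz).
#' @return numeric series of length \code{n} with SD 1.
#' @export
bandLimitedSeries <- function(n, trSeconds, lowHz = 0.01, highHz = 0.1) {
  freqs <- seq(0, n - 1) / (n * trSeconds)
  freqs <- pmin(freqs, 1 / trSeconds - freqs)   # two-sided
  keep <- freqs >= lowHz & freqs <= highHz
  if (!any(keep)) stop("band contains no resolvable frequency")
  spec <- fft(rnorm(n))
  spec[!keep] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

# matrix of independent band-limited series (columns), unnormalized
bandLimitedMatrix <- function(n, m, trSeconds, lowHz = 0.01,
                              highHz = 0.1) {
  freqs <- seq(0, n - 1) / (n * trSeconds)
  freqs <- pmin(freqs, 1 / trSeconds - freqs)
  keep <- freqs >= lowHz & freqs <= highHz
  spec <- mvfft(matrix(rnorm(n * m), n, m))
  spec[!keep, ] <- 0
  Re(mvfft(spec, inverse = TRUE)) / n
}

# per-voxel response amplitudes (voxel x condition), the coupled-voxel
# sets per category, and the truth record
plantStructure <- function(layout, effect) {
  voxels <- sort(union(grayVoxels(layout), whiteVoxels(layout)))
  nVox <- length(voxels)
  beta <- matrix(0, nVox, length(ALL_CONDITIONS),
                 dimnames = list(NULL, ALL_CONDITIONS))
  truth <- list(informative = list(), patterns = list(), gains = list())
  coupled <- list()

  for (rg in regionNames(layout)) {
    idx <- regionVoxels(layout, rg)
    pos <- match(idx, voxels)
    cat <- regionCategory(layout, rg)
    g <- exp(rnorm(length(pos), 0, 0.3))
    truth$gains[[rg]] <- g
    if (cat %in% INTACT_CONDITIONS)
      beta[pos, cat] <- beta[pos, cat] + effect@activationGain * g
    if (regionRole(layout, rg) == "target") {
      nInf <- round(effect@fracInformative * length(pos))
      inf <- sort(sample(length(pos), nInf))
      P <- matrix(0, length(pos), length(INTACT_CONDITIONS),
                  dimnames = list(NULL, INTACT_CONDITIONS))
      if (nInf > 0)
        P[inf, ] <- rnorm(nInf * length(INTACT_CONDITIONS))
      beta[pos, INTACT_CONDITIONS] <- beta[pos, INTACT_CONDITIONS] +
        effect@patternSnr * effect@noiseSd * P
      truth$informative[[rg]] <- list(local = inf, linear = idx[inf])
      truth$patterns[[rg]] <- P
      coupled[[cat]] <- union(coupled[[cat]], idx[inf])
    } else {
      coupled[[cat]] <- union(coupled[[cat]], idx)
    }
  }
  list(voxels = voxels, beta = beta, coupled = coupled, truth = truth)
}

#' Simulate one subject
#'
#' Generates multi-run voxel time series on the layout according to the
#' generative model: per voxel, \code{baseline} plus the HRF-convolved
#' condition boxcars weighted by the voxel's planted response amplitudes
#' (univariate preferred-category gain plus, for informative target
#' voxels, category-specific pattern values), plus noise.  With coupling
#' on, every voxel's noise mixes white noise with a band-limited latent
#' at SD ratio \code{couplingStrength}: coupled voxels (all dedicated
#' seed-region voxels and the informative fraction of each target
#' region) share their category's latent, all other voxels carry a
#' private latent of identical construction.  The total non-task
#' variance is \code{noiseSd^2} in every voxel and the latents are
#' orthogonal to the first-level design span, so coupling is plantable
#' independently of activation amplitude and temporal SNR (see the
#' methods vignette).
#'
#' @param layout a \linkS4class{RegionLayout}.
#' @param design a \linkS4class{DesignSpec}.
#' @param effect an \linkS4class{EffectSpec}.
#' @param seed RNG seed; defaults to \code{effect@seed}.
#' @return a \linkS4class{SubjectDataset} with a filled truth record.
#' @export
simulateSubject <- function(layout, design, effect, seed = effect@seed) {
  withSeed(seed, {
    st <- plantStructure(layout, effect)
    nVox <- length(st$voxels)
    nVol <- design@nVolumes
    a <- effect@couplingStrength / sqrt(1 + effect@couplingStrength^2)
    cats <- names(st$coupled)
    coupledPos <- lapply(st$coupled, function(ix) match(ix, st$voxels))

    motion <- lapply(seq_len(nRuns(design)), function(r)
      apply(matrix(rnorm(nVol * 6, sd = 0.02), nVol, 6), 2, cumsum))

    # With coupling on, every voxel receives the same band-limited
    # variance share a^2: coupled voxels carry the shared per-category
    # latent, all other voxels a private latent of identical
    # construction.  Latents live in the orthogonal complement of the
    # first-level design span (task, drift, motion, intercept) and are
    # scaled so their residual-variance contribution matches the
    # white-noise expectation; by this symmetry, condition betas and
    # activation t values are statistically independent of coupling,
    # which the matched-activation control presupposes.
    designQr <- lapply(seq_len(nRuns(design)), function(r)
      qr(cbind(taskRegressors(design, r),
               driftBasis(nVol, design@trSeconds, 256),
               motion[[r]], 1)))
    resDf <- nVol - ncol(qr.X(designQr[[1]]))
    shapeLatent <- function(qrr, L) {
      L <- qr.resid(qrr, L)
      nrm <- sqrt(colSums(L^2) / resDf)
      sweep(L, 2L, pmax(nrm, 1e-12), "/")
    }
    latents <- lapply(cats, function(cc)
      lapply(seq_len(nRuns(design)), function(r)
        drop(shapeLatent(designQr[[r]],
                         cbind(bandLimitedSeries(nVol,
                                                 design@trSeconds))))))
    names(latents) <- cats

    runs <- vector("list", nRuns(design))
    for (r in seq_len(nRuns(design))) {
      E <- matrix(rnorm(nVol * nVox, sd = effect@noiseSd), nVol, nVox)
      if (a > 0) {
        Lmat <- shapeLatent(designQr[[r]],
                            bandLimitedMatrix(nVol, nVox,
                                              design@trSeconds))
        for (cc in cats) Lmat[, coupledPos[[cc]]] <- latents[[cc]][[r]]
        E <- sqrt(1 - a^2) * E + (a * effect@noiseSd) * Lmat
      }
      X <- taskRegressors(design, r)
      runs[[r]] <- effect@baseline + X %*% t(st$beta) + E
    }

    truth <- st$truth
    truth$coupled <- st$coupled
    truth$latents <- latents
    truth$couplingShare <- a
    new("SubjectDataset", runs = runs, voxels = st$voxels,
        trSeconds = design@trSeconds, layout = layout, design = design,
        motion = motion, truth = truth)
  })
}

#' Simulate a cohort of independent subjects
#'
#' Each subject gets an independently randomized block order and an
#' independent RNG stream derived from the master seed, so a fixed seed
#' reproduces the cohort bit for bit.
#'
#' @param nSubjects number of subjects (at least 2).
#' @param layout a \linkS4class{RegionLayout}.
#' @param effect an \linkS4class{EffectSpec}.
#' @param seed master RNG seed; defaults to \code{effect@seed}.
#' @param design optional shared \linkS4class{DesignSpec}; by default
#'   every subject receives its own randomized block orders.
#' @return list of \linkS4class{SubjectDataset}.
#' @export
simulateCohort <- function(nSubjects, layout, effect,
                           seed = effect@seed, design = NULL) {
  stopifnot(nSubjects >= 2L)
  seeds <- childSeeds(seed, 2L * nSubjects)
  lapply(seq_len(nSubjects), function(i) {
    d <- if (is.null(design))
      makeDesign(seed = seeds[2L * i - 1L]) else design
    simulateSubject(layout, d, effect, seed = seeds[2L * i])
  })
}
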