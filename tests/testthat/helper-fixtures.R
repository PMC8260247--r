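# Shared fixtures, built lazily and cached for the whole test run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# one-category layout small enough for fast unit tests: only region and
# non-gray voxels are simulated
tinyLayout <- function() memo("tinyLayout", {
  makeLayout(c(18L, 10L, 10L), list(
    target = list(center = c(5, 5, 5), radius = 4, role = "target",
                  category = "tools"),
    seed = list(center = c(13, 5, 5), radius = 3, role = "seed",
                category = "tools")),
    minTargetVoxels = 200L)
})

# reduced whole-gray grid for null searchlight calibration
nullSearchLayout <- function() memo("nullSearchLayout", {
  compactLayout(gridDims = c(10L, 10L, 10L),
                targetCenter = c(6, 6, 6), targetRadius = 3,
                seedCenter = c(3, 3, 3), seedRadius = 2,
                minTargetVoxels = 100L)
})

tinySubject <- function() memo("tinySubject", {
  simulateSubject(tinyLayout(), makeDesign(6, seed = 11),
                  effectSpec(seed = 42))
})

tinyPrep <- function() memo("tinyPrep", prepareSubject(tinySubject()))

compactSubject <- function() memo("compactSubject", {
  simulateSubject(compactLayout(), makeDesign(6, seed = 21),
                  effectSpec(seed = 84))
})

compactPrep <- function() memo("compactPrep",
                               prepareSubject(compactSubject()))

# a null subject (no coupling, no patterns, no activation)
tinyNullSubject <- function() memo("tinyNullSubject", {
  simulateSubject(tinyLayout(), makeDesign(6, seed = 12),
                  nullEffectSpec(seed = 77))
})

randomPatternPair <- function(k = 20L) {
  new("PatternPair", splitA = matrix(rnorm(2L * k), 2L, k),
      splitB = matrix(rnorm(2L * k), 2L, k),
      conditions = c("tools", "faces"))
}

# independent reimplementation of the split-half statistic: explicit
# loops over the four correlations
bruteSplitHalf <- function(pair) {
  cc <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2)
    cc[i, j] <- cor(pair@splitA[i, ], pair@splitB[j, ])
  (cc[1, 1] + cc[2, 2]) / 2 - (cc[1, 2] + cc[2, 1]) / 2
}
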