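test_that("split-half accuracy reproduces the hand-computed example", {
  # cond1 = (1,0,0), cond2 = (0,1,0) in both halves: within r = 1,
  # between r = -0.5, accuracy = 1 - (-0.5) = 1.5
  pp <- new("PatternPair",
            splitA = rbind(c(1, 0, 0), c(0, 1, 0)),
            splitB = rbind(c(1, 0, 0), c(0, 1, 0)),
            conditions = c("tools", "faces"))
  expect_equal(splitHalfAccuracy(pp), 1.5)
})

test_that("split-half accuracy is zero for identical patterns and symmetric", {
  set.seed(14)
  x <- rnorm(10)
  same <- new("PatternPair", splitA = rbind(x, x), splitB = rbind(x, x),
              conditions = c("a", "b"))
  expect_equal(splitHalfAccuracy(same), 0)
  pp <- randomPatternPair()
  swapped <- new("PatternPair", splitA = pp@splitB, splitB = pp@splitA,
                 conditions = pp@conditions)
  expect_equal(splitHalfAccuracy(swapped), splitHalfAccuracy(pp))
  # bounded statistic
  for (i in 1:20) {
    a <- splitHalfAccuracy(randomPatternPair())
    expect_gte(a, -2); expect_lte(a, 2)
  }
  # zero-variance pattern flagged missing
  degen <- new("PatternPair", splitA = rbind(rep(1, 5), rnorm(5)),
               splitB = rbind(rnorm(5), rnorm(5)),
               conditions = c("a", "b"))
  expect_true(is.na(splitHalfAccuracy(degen)))
})

test_that("the accuracy matches an explicit-loop oracle", {
  set.seed(15)
  for (i in 1:200) {
    pp <- randomPatternPair(sample(3:40, 1))
    expect_equal(splitHalfAccuracy(pp), bruteSplitHalf(pp),
                 tolerance = 1e-12)
  }
})

test_that("the vectorised subset accuracy agrees with the scalar path", {
  set.seed(16)
  nvox <- 80
  a1 <- rnorm(nvox); a2 <- rnorm(nvox)
  b1 <- rnorm(nvox); b2 <- rnorm(nvox)
  idx <- t(replicate(25, sample(nvox, 30)))
  acc <- connsel:::subsetAccuracy(idx, a1, a2, b1, b2)
  for (i in 1:25) {
    pp <- new("PatternPair",
              splitA = rbind(a1[idx[i, ]], a2[idx[i, ]]),
              splitB = rbind(b1[idx[i, ]], b2[idx[i, ]]),
              conditions = c("x", "y"))
    expect_equal(acc[i], splitHalfAccuracy(pp), tolerance = 1e-12)
  }
})

test_that("patterns are run-averaged, aligned and validated", {
  prep <- tinyPrep()
  s <- tinySubject()
  cols <- connsel:::regionColumns(s, "target")[1:10]
  pp <- extractPatterns(prep$statmaps, cols, list(c(1, 2), c(3, 4)),
                        c("tools", "faces"))
  expect_equal(dim(pp@splitA), c(2L, 10L))
  manual <- (conditionBetas(prep$statmaps[[1]])[c("tools", "faces"),
                                                cols] +
             conditionBetas(prep$statmaps[[2]])[c("tools", "faces"),
                                                cols]) / 2
  expect_equal(unname(pp@splitA), unname(manual))
  # permuting the voxel set permutes both halves identically
  perm <- sample(10)
  pp2 <- extractPatterns(prep$statmaps, cols[perm],
                         list(c(1, 2), c(3, 4)), c("tools", "faces"))
  expect_equal(pp2@splitA, pp@splitA[, perm])
  expect_equal(pp2@splitB, pp@splitB[, perm])
  expect_equal(splitHalfAccuracy(pp2), splitHalfAccuracy(pp))
  expect_error(extractPatterns(prep$statmaps, c(1, 1e6),
                               list(1, 2), c("tools", "faces")),
               "outside")
})

test_that("tSNR implements mean over SD with its invariances", {
  set.seed(17)
  y <- matrix(rnorm(200, mean = 100, sd = 10), 100, 2)
  v <- tsnr(y)
  expect_equal(v, colMeans(y) / apply(y, 2, sd))
  expect_equal(tsnr(2 * y), v)                       # scale invariant
  expect_lt(abs(mean(tsnr(matrix(rnorm(5000), 100, 50)))), 0.5)
  expect_true(is.infinite(tsnr(matrix(1, 10, 1))))
})

test_that("decoding a planted subject ranks selection modes as built", {
  r <- decodeSubject(tinySubject(), prep = tinyPrep())
  agg <- aggregate(accuracy ~ mode, r$decoding, mean)
  acc <- setNames(agg$accuracy, agg$mode)
  expect_gt(acc["most_connected"], acc["least_connected"])
  expect_equal(nrow(r$decoding), 2L * 3L * 3L)  # cmp x fold x mode
  # deterministic end to end
  r2 <- decodeSubject(tinySubject(), prep = tinyPrep())
  expect_identical(r$decoding, r2$decoding)
  # connectivity summary signs mirror the selection
  cz <- aggregate(medianZ ~ mode, r$connectivity, mean)
  mz <- setNames(cz$medianZ, cz$mode)
  expect_gt(mz["most_connected"], 0)
  expect_lt(mz["least_connected"], 0.05)
})

test_that("label permutation nulls the decoding statistic", {
  # shuffling condition labels of the run-wise patterns should leave no
  # category signal: the permutation-mean accuracy sits near zero
  prep <- tinyPrep()
  s <- tinySubject()
  cols <- connsel:::regionColumns(s, "target")
  set.seed(18)
  sel <- sample(cols, 60)
  accs <- vapply(1:100, function(i) {
    perm <- lapply(1:6, function(r) {
      b <- conditionBetas(prep$statmaps[[r]])[, sel]
      b[sample(nrow(b)), ]
    })
    half <- function(rr) (perm[[rr[1]]][c(1, 2), ] +
                            perm[[rr[2]]][c(1, 2), ]) / 2
    pp <- new("PatternPair", splitA = half(c(1, 3)),
              splitB = half(c(2, 4)), conditions = c("c1", "c2"))
    splitHalfAccuracy(pp)
  }, 0)
  expect_lt(abs(mean(accs)), 2 * sd(accs) / sqrt(length(accs)) + 0.05)
})

test_that("decoding accuracy is monotone in pattern amplitude", {
  ly <- tinyLayout()
  snrGrid <- c(0, 0.15, 0.3, 0.6)
  seeds <- connsel:::childSeeds(500L, 2L * 6L * length(snrGrid))
  si <- 0L
  accs <- vapply(snrGrid, function(snr) {
    mean(vapply(1:6, function(i) {
      si <<- si + 2L
      s <- simulateSubject(ly, makeDesign(6, seed = seeds[si - 1L]),
                           effectSpec(patternSnr = snr,
                                      seed = seeds[si]))
      p <- prepareSubject(s)
      inf <- groundTruth(s)$informative$target$local
      cols <- connsel:::regionColumns(s, "target")[inf]
      pp <- extractPatterns(p$statmaps, cols,
                            list(c(1, 3, 5), c(2, 4, 6)),
                            c("tools", "faces"))
      splitHalfAccuracy(pp)
    }, 0))
  }, 0)
  expect_true(all(diff(accs) > -0.02))
  expect_gt(accs[4], accs[1])
})

test_that("cohort decoding returns the documented long format", {
  ly <- tinyLayout()
  cohort <- simulateCohort(2, ly, effectSpec(seed = 19))
  tab <- decodeAll(cohort, modes = c("most_connected",
                                     "least_connected"))
  expect_setequal(names(tab), c("subject", "region", "category",
                                "comparison", "mode", "fold",
                                "accuracy"))
  expect_setequal(unique(tab$comparison), c("TvF", "TvP"))
  fa <- foldAverage(tab)
  expect_equal(nrow(fa), nrow(tab) / 3L)
  expect_true(all(abs(fa$accuracy) <= 2))
})
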