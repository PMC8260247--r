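test_that("task regression removes exactly the modelled structure", {
  d <- makeDesign(1, seed = 14)
  dm <- buildDesignMatrix(d, 1)
  X <- dm@matrix
  set.seed(5)
  # data built purely from task regressors fit perfectly
  Y <- X %*% matrix(rnorm(ncol(X) * 20), ncol(X), 20)
  expect_lt(max(abs(taskRegress(Y, dm))), 1e-8)
  # residuals are uncorrelated with every regressor
  Y2 <- matrix(rnorm(88 * 20), 88, 20)
  res <- taskRegress(Y2, dm)
  vary <- X[, apply(X, 2, sd) > 0]
  expect_lt(max(abs(cor(res, vary))), 1e-10)
  # rank deficiency is an error
  M <- cbind(X, X[, 1, drop = FALSE])
  dm2 <- new("DesignMatrix", matrix = `colnames<-`(M,
               c(colnames(X), "dup")),
             conditionNames = dm@conditionNames, trSeconds = 2)
  expect_error(taskRegress(Y2, dm2), "rank deficient")
})

test_that("planted coupling structure survives task regression", {
  # the same noise realization with and without task signal must leave
  # the same residual correlation structure once the task is projected
  # out: the latent coupling is untouched by task regression
  d <- makeDesign(6, seed = 15)
  sQuiet <- simulateSubject(tinyLayout(), d,
                            effectSpec(activationGain = 0,
                                       patternSnr = 0, seed = 16))
  sTask <- simulateSubject(tinyLayout(), d,
                           effectSpec(activationGain = 2,
                                      patternSnr = 0.5, seed = 16))
  inf <- groundTruth(sQuiet)$informative$target$local
  cols <- connsel:::regionColumns(sQuiet, "target")[inf[1:40]]
  resid <- function(s) do.call(rbind, lapply(seq_len(6), function(r)
    taskRegress(s@runs[[r]][, cols],
                buildDesignMatrix(s@design, r,
                                  motion = s@motion[[r]]))))
  c1 <- cor(resid(sQuiet))
  c2 <- cor(resid(sTask))
  off <- row(c1) != col(c1)
  expect_lt(abs(mean(c2[off]) - mean(c1[off])) / mean(c1[off]), 0.02)
  # and the planted positive coupling is still there
  expect_gt(mean(c2[off]), 0.1)
})

test_that("the band-pass filter meets its gain contract", {
  tr <- 2
  t <- (0:87) * tr
  pass <- sin(2 * pi * 0.05 * t)
  out <- bandpassFilter(pass, trSeconds = tr)
  expect_lt(abs(max(abs(out)) - 1), 0.1)       # passband within 10%
  stopb <- sin(2 * pi * 0.2 * t)
  out2 <- bandpassFilter(stopb, trSeconds = tr)
  expect_lt(max(abs(out2)), 0.2)               # 2x upper edge attenuated
  expect_lt(max(abs(bandpassFilter(rep(7, 88), trSeconds = tr))), 1e-10)
  expect_error(bandpassFilter(pass, highHz = 0.3, trSeconds = tr),
               "Nyquist")
})

test_that("connectivity profiles implement the Fisher-z statistic", {
  set.seed(6)
  x <- rnorm(176)
  # a seed identical to the target voxel hits the clipping bound
  prof <- connectivityProfile(cbind(x), cbind(x))
  expect_equal(prof@zMatrix[1, 1], atanh(1 - 1e-7))
  # closed form: r = 0.5 -> z = 0.5493
  y <- scale(cbind(x))
  z <- scale(cbind(rnorm(176)))
  z <- drop(0.5 * y + sqrt(0.75) * scale(drop(z - y * drop(cor(y, z)))))
  r <- cor(x, z)
  prof2 <- connectivityProfile(cbind(x), cbind(z))
  expect_equal(prof2@zMatrix[1, 1], atanh(r))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
})

test_that("null connectivity is centred at zero with the Fisher variance", {
  set.seed(7)
  n <- 176
  tgt <- matrix(rnorm(n * 50), n, 50)
  sds <- matrix(rnorm(n * 20), n, 20)
  prof <- connectivityProfile(tgt, sds)
  expect_lt(abs(mean(prof@zMatrix)), 3 / sqrt(1000 * (n - 3)))
})

test_that("profiles respect antisymmetry, ordering invariance and flags", {
  set.seed(8)
  tgt <- matrix(rnorm(176 * 5), 176, 5)
  s1 <- matrix(rnorm(176 * 3), 176, 3)
  s2 <- matrix(rnorm(176 * 4), 176, 4)
  p <- connectivityProfile(tgt, list(a = s1, b = s2))
  tgtNeg <- tgt; tgtNeg[, 2] <- -tgtNeg[, 2]
  pNeg <- connectivityProfile(tgtNeg, list(a = s1, b = s2))
  expect_equal(pNeg@zMatrix[2, ], -p@zMatrix[2, ])
  pSwap <- connectivityProfile(tgt, list(b = s2, a = s1))
  expect_equal(meanZ(pSwap), meanZ(p))
  # zero-variance target voxel flagged ineligible
  tgt0 <- tgt; tgt0[, 3] <- 5
  p0 <- connectivityProfile(tgt0, s1)
  expect_false(p0@eligible[3])
  expect_true(all(is.na(p0@zMatrix[3, ])))
})

test_that("subject residuals are band-limited and task-free", {
  s <- tinySubject()
  res <- tinyPrep()$residuals
  expect_length(res, 6L)
  expect_equal(dim(res[[1]]), dim(s@runs[[1]]))
  # DC removed
  expect_lt(max(abs(colMeans(res[[1]]))), 1e-8)
})
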