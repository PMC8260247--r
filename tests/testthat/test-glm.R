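test_that("the canonical HRF has the conventional double-gamma shape", {
  h <- canonicalHrf(0.1)
  expect_equal(h[1], 0)                      # gamma density is 0 at t=0
  expect_equal((which.max(h) - 1) * 0.1, 5)  # peaks near 5 s
  expect_equal(max(h), 1)                    # peak-normalized
  post <- h[seq_along(h) > which.max(h)]
  expect_lt(min(post), 0)                    # undershoot present
})

test_that("design matrices have the documented column structure", {
  d <- makeDesign(1, seed = 2)
  dm <- buildDesignMatrix(d, 1, motion = matrix(rnorm(88 * 6), 88, 6))
  expect_equal(nrow(dm@matrix), 88L)
  cn <- colnames(dm@matrix)
  expect_length(dm@conditionNames, 8L)       # 4 intact + 4 scrambled
  expect_equal(sum(grepl("^motion", cn)), 6L)
  expect_equal(sum(cn == "intercept"), 1L)
  # a 256 s cutoff admits exactly one estimable slow cosine in 176 s
  expect_equal(sum(grepl("^drift", cn)), 1L)
  # cutoff beyond twice the run length leaves no drift term
  dm2 <- buildDesignMatrix(d, 1, hpCutoffSeconds = 400)
  expect_equal(sum(grepl("^drift", colnames(dm2@matrix))), 0L)
})

test_that("a block past the end of the run is rejected", {
  d <- makeDesign(1, seed = 2)
  d@runs[[1]]$onset[12] <- 173
  expect_error(taskRegressors(d, 1), "past the end")
})

test_that("OLS recovers planted betas exactly on noiseless data", {
  d <- makeDesign(1, seed = 4)
  dm <- buildDesignMatrix(d, 1)
  X <- dm@matrix
  set.seed(1)
  B <- matrix(rnorm(ncol(X) * 30), ncol(X), 30)
  sm <- fitGlmRun(X %*% B, dm)
  expect_lt(max(abs(sm@coef - B)), 1e-8)
  expect_equal(sm@residualDf, nrow(X) - ncol(X))
})

test_that("pure-noise betas are centred on zero", {
  d <- makeDesign(1, seed = 5)
  dm <- buildDesignMatrix(d, 1)
  set.seed(2)
  sm <- fitGlmRun(matrix(rnorm(88 * 1000), 88, 1000), dm)
  b <- conditionBetas(sm)["tools", ]
  expect_lt(abs(mean(b)), 3 * sd(b) / sqrt(length(b)))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  d <- makeDesign(1, seed = 6)
  dm <- buildDesignMatrix(d, 1)
  M <- cbind(dm@matrix, dup_tools = dm@matrix[, "tools"])
  dm2 <- new("DesignMatrix", matrix = M,
             conditionNames = dm@conditionNames, trSeconds = 2)
  expect_error(fitGlmRun(matrix(rnorm(88 * 3), 88, 3), dm2),
               "dup_tools|tools")
})

test_that("contrast t maps behave as planted", {
  d <- makeDesign(1, seed = 7)
  dm <- buildDesignMatrix(d, 1)
  X <- dm@matrix
  set.seed(3)
  B <- matrix(0, ncol(X), 50)
  rownames(B) <- colnames(X)
  B["tools", 25] <- 2          # one voxel responds only to tools
  Y <- X %*% B + matrix(rnorm(88 * 50, sd = 0.5), 88, 50)
  sm <- fitGlmRun(Y, dm)
  t1 <- contrastTmap(sm, categoryContrast("tools"))
  expect_equal(which.max(t1), 25L)
  expect_gt(t1[25], 0)
  expect_equal(contrastTmap(sm, rep(0, 8)), numeric(50))
  # determinism: same data, same map
  expect_identical(t1, contrastTmap(fitGlmRun(Y, dm),
                                    categoryContrast("tools")))
})

test_that("zero-residual-variance voxels are flagged undefined", {
  d <- makeDesign(1, seed = 8)
  dm <- buildDesignMatrix(d, 1)
  Y <- dm@matrix %*% matrix(1, ncol(dm@matrix), 2)  # perfect fit
  sm <- fitGlmRun(Y, dm)
  expect_true(all(is.na(contrastTmap(sm, categoryContrast("tools")))))
})

test_that("OLS invariances hold", {
  d <- makeDesign(1, seed = 9)
  set.seed(4)
  motion <- matrix(rnorm(88 * 6), 88, 6)
  dm <- buildDesignMatrix(d, 1, motion = motion)
  Y <- matrix(rnorm(88 * 40), 88, 40)
  sm <- fitGlmRun(Y, dm)
  # residuals orthogonal to every design column
  res <- Y - dm@matrix %*% sm@coef
  dots <- crossprod(dm@matrix, res)
  norms <- outer(sqrt(colSums(dm@matrix^2)), sqrt(colSums(res^2)))
  expect_lt(max(abs(dots) / norms), 1e-6)
  # t maps invariant to positive rescaling of the data
  t1 <- contrastTmap(sm, categoryContrast("faces"))
  t2 <- contrastTmap(fitGlmRun(3.7 * Y, dm), categoryContrast("faces"))
  expect_equal(t1, t2, tolerance = 1e-10)
  # noise-only motion columns leave noiseless betas untouched
  dmPlain <- buildDesignMatrix(d, 1)
  B <- matrix(rnorm(ncol(dmPlain@matrix) * 10), ncol(dmPlain@matrix), 10)
  Yn <- dmPlain@matrix %*% B
  b1 <- conditionBetas(fitGlmRun(Yn, dmPlain))
  b2 <- conditionBetas(fitGlmRun(Yn, buildDesignMatrix(d, 1,
                                                       motion = motion)))
  expect_lt(max(abs(b1 - b2)), 1e-8)
})
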