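test_that("the paired t test matches closed forms", {
  a <- c(3, 4, 5); b <- c(2, 2, 2)   # differences 1, 2, 3
  r <- pairedT(a, b)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  same <- pairedT(1:5, 1:5)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  rn <- pairedT(b, a)
  expect_equal(rn$t, -r$t); expect_equal(rn$p, r$p)
  # agrees with the stats oracle
  set.seed(25)
  x <- rnorm(12); y <- rnorm(12)
  tt <- t.test(x, y, paired = TRUE)
  r2 <- pairedT(x, y)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  expect_error(pairedT(c(1, 2), c(0, 1)), "zero-variance")
})

test_that("Bonferroni correction divides alpha and only tightens decisions", {
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 4), 0.0125)
  expect_lte(bonferroniThreshold(0.05, 7), 0.05)
})

test_that("a two-level repeated-measures ANOVA reduces to the paired t", {
  set.seed(26)
  d <- data.frame(subject = rep(1:10, each = 2),
                  cond = rep(c("a", "b"), 10),
                  accuracy = rnorm(20))
  an <- rmAnova(d, "accuracy", "cond")
  tt <- pairedT(d$accuracy[d$cond == "a"], d$accuracy[d$cond == "b"])
  expect_equal(an$F[an$term == "cond"], tt$t^2, tolerance = 1e-10)
  expect_equal(an$df1[an$term == "cond"], 1)
  expect_equal(an$df2[an$term == "cond"], 9)
  expect_equal(an$p[an$term == "cond"], tt$p, tolerance = 1e-10)
})

test_that("rmAnova handles three factors, constants, dropouts and permutation", {
  set.seed(27)
  g <- expand.grid(subject = 1:8, A = c("x", "y"), B = c("p", "q"),
                   C = c("u", "v"))
  g$accuracy <- rnorm(nrow(g)) + as.numeric(g$A == "x")
  an <- rmAnova(g, "accuracy", c("A", "B", "C"))
  expect_equal(nrow(an), 7L)          # 3 mains + 3 two-way + 1 three-way
  expect_true(all(an$F >= 0))
  expect_true(all(an$petaSq >= 0 & an$petaSq <= 1))
  expect_gt(an$F[an$term == "A"], an$F[an$term == "B"])
  # row order is irrelevant
  an2 <- rmAnova(g[sample(nrow(g)), ], "accuracy", c("A", "B", "C"))
  expect_equal(an, an2)
  # constant dv gives F = 0
  g$accuracy <- 1
  an3 <- rmAnova(g, "accuracy", c("A", "B", "C"))
  expect_true(all(an3$F == 0))
  # subjects with missing cells are dropped
  g2 <- expand.grid(subject = 1:5, A = c("x", "y"))
  g2$accuracy <- rnorm(10)
  g2 <- g2[-1, ]
  an4 <- rmAnova(g2, "accuracy", "A")
  expect_equal(attr(an4, "nSubjects"), 4L)
  expect_error(rmAnova(g2[g2$subject %in% 1:2, ], "accuracy", "A"),
               "fewer than 2")
})

test_that("TFCE passes its structural checks", {
  dims <- c(8L, 8L, 8L)
  mask <- seq_len(prod(dims))
  expect_equal(tfce(numeric(length(mask)), dims, mask),
               numeric(length(mask)))
  # single positive voxel approaches the closed form v^(H+1)/(H+1)
  v <- 2.4
  vals <- numeric(length(mask))
  ctr <- linearIndex(cbind(4, 4, 4), dims)
  vals[ctr] <- v
  enh <- tfce(vals, dims, mask, E = 0.5, H = 2, nSteps = 5000)
  expect_equal(enh[ctr], v^3 / 3, tolerance = 1e-2)
  expect_true(all(enh[-ctr] == 0))
  # monotone under doubling
  set.seed(28)
  m <- pmax(rnorm(length(mask)), 0)
  e1 <- tfce(m, dims, mask)
  e2 <- tfce(2 * m, dims, mask)
  expect_true(all(e2 >= e1 - 1e-12))
  # clusters use face connectivity: two diagonal voxels stay separate
  vals2 <- numeric(length(mask))
  a <- linearIndex(cbind(2, 2, 2), dims)
  b <- linearIndex(cbind(3, 3, 2), dims)
  vals2[c(a, b)] <- 1
  e3 <- tfce(vals2, dims, mask, nSteps = 2000)
  expect_equal(e3[a], 1 / 3, tolerance = 1e-2)   # extent stays 1
  # joined by a face neighbor, enhancement grows
  vals2[linearIndex(cbind(3, 2, 2), dims)] <- 1
  e4 <- tfce(vals2, dims, mask, nSteps = 2000)
  expect_gt(e4[a], e3[a])
})

test_that("sign-flip group maps are deterministic with bounded p values", {
  set.seed(29)
  dims <- c(6L, 6L, 6L)
  mask <- seq_len(prod(dims))
  diffs <- matrix(rnorm(10 * length(mask)), 10, length(mask))
  gm <- signFlipGroupMap(diffs, dims, mask, nPerm = 300, seed = 5)
  expect_true(all(gm@p >= 1 / 301 & gm@p <= 1))
  expect_true(all(is.finite(gm@z)))
  gm2 <- signFlipGroupMap(diffs, dims, mask, nPerm = 300, seed = 5)
  expect_identical(gm@z, gm2@z)
  expect_warning(signFlipGroupMap(diffs, dims, mask, nPerm = 50,
                                  seed = 6),
                 "unstable")
})

test_that("a strong planted blob survives FWE correction where planted", {
  set.seed(30)
  dims <- c(8L, 8L, 8L)
  mask <- seq_len(prod(dims))
  blob <- dilateVoxels(linearIndex(cbind(4, 4, 4), dims), dims, 1)
  diffs <- matrix(rnorm(12 * length(mask), sd = 0.1), 12, length(mask))
  diffs[, blob] <- diffs[, blob] + 1
  gm <- signFlipGroupMap(diffs, dims, mask, nPerm = 500, seed = 7)
  supra <- suprathresholdVoxels(gm)
  expect_gt(length(supra), 0L)
  expect_true(all(supra %in% dilateVoxels(blob, dims, 1)))
  expect_true(any(blob %in% supra))
})
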