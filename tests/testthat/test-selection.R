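test_that("the split scheme partitions six runs into three two-run folds", {
  sc <- makeSplitScheme(6, seed = 1)
  expect_length(sc@splits, 3L)
  expect_setequal(unlist(sc@splits), 1:6)
  for (f in sc@folds) {
    expect_length(f$selection, 2L)
    expect_length(unlist(f$decoding), 4L)
    expect_length(intersect(f$selection, unlist(f$decoding)), 0L)
  }
  expect_identical(makeSplitScheme(6, seed = 1), sc)
  expect_setequal(unlist(lapply(sc@folds, `[[`, "selection")), 1:6)
  expect_error(makeSplitScheme(4), "6 runs")
  sc2 <- makeSplitScheme(4, splits = list(1:2, 3, 4))
  expect_length(sc2@folds, 3L)
})

test_that("top-k selection matches the brute-force sort", {
  scores <- c(0.1, 0.5, -0.2, 0.3)
  most <- selectTopK(scores, 2, "most")
  expect_equal(voxelIndices(most), c(2L, 4L))
  least <- selectTopK(scores, 2, "least")
  expect_equal(voxelIndices(least), c(3L, 1L))
  expect_equal(selectionMode(most), "most_connected")
  # randomised agreement with a full-sort oracle
  set.seed(9)
  for (i in 1:50) {
    s <- rnorm(60)
    k <- sample(5:30, 1)
    expect_equal(voxelIndices(selectTopK(s, k, "most",
                                         requireDisjoint = FALSE)),
                 order(-s)[seq_len(k)])
  }
})

test_that("top-k obeys ties, eligibility and the disjointness contract", {
  # ties broken by ascending voxel index
  expect_equal(voxelIndices(selectTopK(rep(1, 10), 3, "most",
                                       requireDisjoint = FALSE)), 1:3)
  # k equal to the eligible count returns everything
  s <- rnorm(7)
  expect_setequal(voxelIndices(selectTopK(s, 7, "most",
                                          requireDisjoint = FALSE)), 1:7)
  expect_error(selectTopK(rnorm(10), 6, "most"), "2k")
  # most/least sets disjoint whenever 2k fits, min(most) >= max(least)
  set.seed(10)
  for (i in 1:20) {
    sc <- rnorm(50)
    m <- selectTopK(sc, 20, "most")
    l <- selectTopK(sc, 20, "least")
    expect_length(intersect(voxelIndices(m), voxelIndices(l)), 0L)
    expect_gte(min(sc[voxelIndices(m)]), max(sc[voxelIndices(l)]))
  }
  # ineligible voxels are never selected
  sc <- rnorm(30); elig <- sc < 1
  m <- selectTopK(sc, 5, "most", eligible = elig)
  expect_true(all(elig[voxelIndices(m)]))
})

test_that("most-activated selection tracks the t map and tie rule", {
  tmap <- c(rep(0, 9), 10)
  vs <- selectMostActivated(tmap, 1, contrast = "TvF",
                            requireDisjoint = FALSE)
  expect_equal(voxelIndices(vs), 10L)
  expect_equal(selectionMode(vs), "most_activated")
  flat <- selectMostActivated(rep(2, 12), 4, requireDisjoint = FALSE)
  expect_equal(voxelIndices(flat), 1:4)
})

test_that("matching retains ~90% of draws when activation is independent", {
  # large pool so the median split leaves per-draw matching t close to
  # its null distribution: retention approximates P(p > 0.10) = 0.90
  set.seed(11)
  z <- rnorm(4000)
  tv <- rnorm(4000)
  mp <- matchedActivationPairs(z, tv, k = 20, "liberal",
                               nDraws = 10000, seed = 3)
  expect_equal(retentionRate(mp), 0.90, tolerance = 0.025)
})

test_that("a perfect activation-connectivity confound defeats strict matching", {
  set.seed(12)
  z <- rnorm(600)
  mp <- matchedActivationPairs(z, z, k = 100, "strict",
                               nDraws = 5000, seed = 4)
  expect_lt(retentionRate(mp), 0.001)
})

test_that("degenerate equal activation passes every draw as t = 0", {
  z <- rnorm(400)
  mp <- matchedActivationPairs(z, rep(1, 400), k = 50, "liberal",
                               nDraws = 500, seed = 5)
  expect_equal(nRetained(mp), 500L)
  expect_true(all(mp@tStat == 0))
})

test_that("retained pairs re-pass their threshold when recomputed", {
  set.seed(13)
  z <- rnorm(500)
  tv <- rnorm(500)
  for (mode in c("liberal", "intermediate", "strict")) {
    mp <- matchedActivationPairs(z, tv, k = 80, mode, nDraws = 2000,
                                 seed = 6)
    expect_gt(nRetained(mp), 0L)
    for (i in seq_len(min(nRetained(mp), 50L))) {
      a <- tv[mp@strong[i, ]]
      b <- tv[mp@weak[i, ]]
      tt <- unname(t.test(a, b, var.equal = TRUE)$statistic)
      expect_equal(tt, mp@tStat[i], tolerance = 1e-10)
      ok <- switch(mode,
        liberal = 2 * pt(-abs(tt), 158) > 0.10,
        intermediate = tt >= -0.5 && tt <= 0.5,
        strict = tt >= -0.5 && tt <= 0)
      expect_true(ok)
    }
    # strong subsets come from the upper half, weak from the lower
    medz <- median(z)
    expect_true(all(z[mp@strong] >= medz))
    expect_true(all(z[mp@weak] <= medz))
  }
})

test_that("matching draws are reproducible and halves too small return empty", {
  z <- rnorm(300); tv <- rnorm(300)
  m1 <- matchedActivationPairs(z, tv, k = 100, "liberal",
                               nDraws = 200, seed = 7)
  m2 <- matchedActivationPairs(z, tv, k = 100, "liberal",
                               nDraws = 200, seed = 7)
  expect_identical(m1@strong, m2@strong)
  expect_identical(m1@tStat, m2@tStat)
  empty <- matchedActivationPairs(rnorm(150), rnorm(150), k = 100,
                                  "liberal", nDraws = 50, seed = 8)
  expect_equal(nRetained(empty), 0L)
  vs <- pairVoxelSets(m1, 1)
  expect_equal(selectionMode(vs$strong), "matched_strong")
  expect_length(voxelIndices(vs$weak), 100L)
})

test_that("voxel sets round-trip through JSON", {
  vs <- selectTopK(rnorm(50), 10, "most", requireDisjoint = FALSE,
                   foldId = 2L)
  f <- tempfile(fileext = ".json")
  writeVoxelSetJson(list(vs), f)
  back <- readVoxelSetJson(f)
  expect_length(back, 1L)
  expect_identical(voxelIndices(back[[1]]), voxelIndices(vs))
  expect_identical(back[[1]]@mode, "most_connected")
  expect_identical(back[[1]]@foldId, 2L)
  unlink(f)
})
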