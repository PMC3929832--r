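test_that("pooled t statistic matches the closed form and stats::t.test", {
  # closed form: sp2 = 1, t = -3/sqrt(2/3) = -3.674235, p = 2*pt(t, 4)
  r <- ttestStatistic(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4L)
  expect_equal(r$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(r$p, 0.0213, tolerance = 1e-2)

  set.seed(6)
  a <- rnorm(12); b <- rnorm(15, 0.4)
  r2 <- ttestStatistic(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-12)

  same <- ttestStatistic(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # zero pooled variance: flagged; shifted constant = infinite separation
  degen <- ttestStatistic(c(1, 1, 1), c(2, 2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 0)
  flat <- ttestStatistic(c(1, 1, 1), c(1, 1, 1))
  expect_true(flat$degenerate)
  expect_equal(flat$p, 1)
})

test_that("leave-10-out folds are stratified groups of exactly ten", {
  set.seed(2)
  X <- matrix(rnorm(60 * 5), 60)
  y <- rep(c(-1, 1), each = 30)
  X[, 1] <- 0.1 * X[, 1] + 2 * y   # 40-sigma class separation
  rep_ <- leave10outAccuracy(X, y, foldSeed = 4L)
  expect_equal(rep_@nFolds, 6L)
  expect_length(foldAccuracies(rep_), 6L)
  expect_equal(accuracy(rep_), mean(foldAccuracies(rep_)), tolerance = 1e-9)
  expect_equal(accuracy(rep_), 100)          # separable by construction
  expect_error(leave10outAccuracy(X[1:15, ], y[1:15]), "at least 20")
})

test_that("null-label accuracy is centered near chance", {
  set.seed(10)
  accs <- sapply(1:12, function(s) {
    X <- matrix(rnorm(60 * 30), 60)
    y <- rep(c(-1, 1), 30)
    accuracy(leave10outAccuracy(X, y, foldSeed = s))
  })
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})

test_that("accuracy is invariant to feature order", {
  inst <- randomInstance(40, 8, sep = 0.6, seed = 3)
  a1 <- accuracy(leave10outAccuracy(inst$X, inst$y, foldSeed = 7L))
  perm <- sample(8)
  a2 <- accuracy(leave10outAccuracy(inst$X[, perm], inst$y, foldSeed = 7L))
  expect_equal(a1, a2)
})

test_that("t-test selector thresholds p and takes top fractions", {
  coh <- generateCohort(phantomParams(dims = c(14L, 14L, 14L),
                                      nPerClass = 10L, effectSize = 0.5,
                                      roiSpec = matrix(c(7, 7, 7, 2), 1),
                                      noiseSd = 0, seed = 2L))
  fm <- buildFeatureMatrix(coh)
  # zero noise: truth features perfectly separated, p ~ 0 inside
  sel <- ttestSelect(fm, mode = "p_threshold", alphaOrFraction = 0.05)
  tm <- truthMask(coh)
  selVol <- maskAsVolume(sel)
  expect_true(all(selVol[tm]))

  selTop <- ttestSelect(matrix(rnorm(200), 20), rep(c(-1, 1), 10),
                        mode = "top_fraction", alphaOrFraction = 0.2)
  expect_length(featureIndices(selTop), 2L)
  set.seed(30)
  expect_warning(
    ttestSelect(matrix(rnorm(100), 10), rep(c(-1, 1), 5),
                mode = "p_threshold", alphaOrFraction = 1e-12),
    "empty")
})

test_that("selector comparison mirrors the report structure", {
  coh <- generateCohort(phantomParams(dims = c(14L, 14L, 14L),
                                      nPerClass = 15L, effectSize = 0.5,
                                      roiSpec = matrix(c(7, 7, 7, 2.5), 1),
                                      noiseSd = 0.1, smoothFwhm = 0,
                                      seed = 17L))
  scheme <- makeSlidingSubsets(15L, 12L, 9L, orderSeed = 1L)   # 2 sets
  cmp <- compareSelectors(coh, scheme, tau = 0.1,
                          consensusThresholds = c(0.5, 1.0), foldSeed = 2L)
  expect_s3_class(cmp, "data.frame")
  expect_setequal(unique(cmp$scope),
                  c("per_subset", "pooled", "pooled_consensus"))
  expect_true(all(cmp$accuracy_pct >= 0 & cmp$accuracy_pct <= 100,
                  na.rm = TRUE))
  expect_true(any(grepl("not a strict CV", cmp$note)))
  # strong localized effect: both pipelines should classify well pooled
  pooled <- cmp[cmp$scope != "per_subset", ]
  expect_true(all(pooled$accuracy_pct > 80, na.rm = TRUE))
})

test_that("identical feature sets give selector-independent accuracy", {
  coh <- generateCohort(phantomParams(dims = c(12L, 12L, 12L),
                                      nPerClass = 12L, effectSize = 0.4,
                                      roiSpec = matrix(c(6, 6, 6, 2), 1),
                                      noiseSd = 0.08, smoothFwhm = 0,
                                      seed = 23L))
  fm <- buildFeatureMatrix(coh)
  tm <- truthMask(coh)
  lin <- (voxelMap(fm)[, 3] - 1) * 144 + (voxelMap(fm)[, 2] - 1) * 12 +
         voxelMap(fm)[, 1]
  idx <- which(tm[lin])
  a1 <- accuracy(leave10outAccuracy(featureValues(fm)[, idx],
                                    featureLabels(fm), foldSeed = 5L))
  a2 <- accuracy(leave10outAccuracy(featureValues(fm)[, idx],
                                    featureLabels(fm), foldSeed = 5L))
  expect_equal(a1, a2)
})
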