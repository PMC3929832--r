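test_that("sliding-window arithmetic matches the closed form", {
  expect_equal(nSets(makeSlidingSubsets(185L, 30L, 25L)), 32L)
  s1 <- makeSlidingSubsets(30L, 30L, 25L)
  expect_equal(nSets(s1), 1L)
  expect_setequal(s1[[1]]$normal, 1:30)
  s3 <- makeSlidingSubsets(40L, 30L, 25L, orderSeed = 2L)
  expect_equal(nSets(s3), 3L)
  # consecutive windows advance by window - overlap = 5 over the shuffle
  expect_length(intersect(s3[[1]]$normal, s3[[2]]$normal), 25L)
  expect_length(intersect(s3[[2]]$normal, s3[[3]]$normal), 25L)
  expect_error(makeSlidingSubsets(20L, 30L, 25L), "exceeds")
  expect_error(makeSlidingSubsets(40L, 30L, 30L), "overlap")
})

test_that("subset windows are reproducible from the order seed", {
  a <- makeSlidingSubsets(50L, 20L, 15L, orderSeed = 9L)
  b <- makeSlidingSubsets(50L, 20L, 15L, orderSeed = 9L)
  c <- makeSlidingSubsets(50L, 20L, 15L, orderSeed = 10L)
  expect_identical(a@subsets, b@subsets)
  expect_false(identical(a@subsets, c@subsets))
})

test_that("consensus counts equal the sum of per-subset selections", {
  coh <- generateCohort(phantomParams(dims = c(14L, 14L, 14L),
                                      nPerClass = 12L, effectSize = 0.5,
                                      roiSpec = matrix(c(7, 7, 7, 2.5), 1),
                                      noiseSd = 0.08, smoothFwhm = 1,
                                      seed = 31L))
  scheme <- makeSlidingSubsets(12L, 8L, 4L, orderSeed = 1L)
  expect_equal(nSets(scheme), 2L)
  u <- featureUniverse(coh)
  cm <- runConsensus(coh, scheme, tau = 0.1, fraction = 0.2, universe = u)

  # recount oracle: rebuild each subset's mask independently and sum
  recount <- integer(length(counts(cm)))
  for (k in 1:2) {
    sub <- scheme[[k]]
    fm <- buildFeatureMatrix(coh, u, c(sub$normal, sub$ad))
    res <- svmRFE(fm, tau = 0.1)
    sel <- featureIndices(selectTopFraction(res, 0.2))
    recount[sel] <- recount[sel] + 1L
  }
  expect_identical(counts(cm), recount)

  # planted region is selected more consistently than background
  tm <- truthMask(coh)
  lin <- (voxelMap(cm)[, 3] - 1) * 14 * 14 +
         (voxelMap(cm)[, 2] - 1) * 14 + voxelMap(cm)[, 1]
  inTruth <- tm[lin]
  expect_gt(mean(counts(cm)[inTruth]), mean(counts(cm)[!inTruth]))
})

test_that("fraction 1.0 saturates every in-universe feature", {
  coh <- generateCohort(tinyParams(seed = 41L))
  scheme <- makeSlidingSubsets(4L, 3L, 2L, orderSeed = 1L)
  cm <- runConsensus(coh, scheme, tau = 0.5, fraction = 1.0)
  expect_true(all(counts(cm) == nSets(cm)))
})

test_that("counts are invariant to subject order within a subset", {
  coh <- generateCohort(phantomParams(dims = c(12L, 12L, 12L),
                                      nPerClass = 10L, effectSize = 0.4,
                                      roiSpec = matrix(c(6, 6, 6, 2), 1),
                                      noiseSd = 0.1, smoothFwhm = 0,
                                      seed = 5L))
  u <- featureUniverse(coh)
  sub <- list(normal = 1:8, ad = 11:18)
  fm1 <- buildFeatureMatrix(coh, u, c(sub$normal, sub$ad))
  perm <- c(sample(1:8), sample(9:16))
  fm2 <- buildFeatureMatrix(coh, u, c(sub$normal, sub$ad)[perm])
  s1 <- featureIndices(selectTopFraction(svmRFE(fm1, tau = 0.1), 0.2))
  s2 <- featureIndices(selectTopFraction(svmRFE(fm2, tau = 0.1), 0.2))
  expect_setequal(s1, s2)
})

test_that("binomial null has the right closed-form properties", {
  h <- binomialNull(32, 0.2, M = 1000)
  expect_equal(sum(h$pmf), 1, tolerance = 1e-12)
  expect_equal(sum(h$k * h$pmf), 6.4, tolerance = 1e-12)   # mean n*p
  expect_equal(h$pmf[h$k == 0], 0.8^32, tolerance = 1e-15)
  expect_equal(sum(h$expected), 1000, tolerance = 1e-9)
  expect_error(binomialNull(32, 0), "p must")
})

test_that("binomial null matches Monte-Carlo independent uniform selection", {
  M <- 1000L; nset <- 32L; p <- 0.2
  k <- as.integer(round(p * M))
  reps <- 10000L
  set.seed(77)
  # each replicate tracks one feature: how many of 32 sets pick it when
  # each set draws k of M uniformly; aggregate the count histogram
  bins <- integer(nset + 1L)
  track <- 25L   # features tracked per replicate (marginals are exchangeable)
  for (r in seq_len(reps / track)) {
    cnt <- integer(track)
    for (s in seq_len(nset)) {
      sel <- sample.int(M, k)
      cnt <- cnt + as.integer(seq_len(track) %in% sel)
    }
    tab <- tabulate(cnt + 1L, nbins = nset + 1L)
    bins <- bins + tab
  }
  nTracked <- (reps / track) * track
  h <- binomialNull(nset, p, M = nTracked)
  se <- sqrt(nTracked * h$pmf * (1 - h$pmf))
  dev <- abs(bins - h$expected)
  # per-bin comparison where the normal SE is meaningful (expected >= 5,
  # Cochran's rule); the sparse far tail is pooled into one comparison
  dense <- h$expected >= 5
  expect_true(all(dev[dense] <= 3 * se[dense]))
  pTail <- sum(h$pmf[!dense])
  expect_lte(abs(sum(bins[!dense]) - sum(h$expected[!dense])),
             3 * sqrt(nTracked * pTail * (1 - pTail)))
})

test_that("consensus thresholding selects by minimum set count", {
  vm <- cbind(1:3, 1L, 1L); storage.mode(vm) <- "integer"
  cm <- new("ConsensusMap", counts = c(5L, 20L, 31L), nSets = 32L,
            fraction = 0.2, voxelMap = vm, dims = c(3L, 1L, 1L))
  expect_equal(featureIndices(thresholdConsensus(cm, 24)), 3L)  # 75% of 32
  expect_length(thresholdConsensus(cm, 0), 3L)
  expect_equal(featureIndices(thresholdConsensus(cm, 32)), integer(0))
  expect_error(thresholdConsensus(cm, 40), "minSets")
})

test_that("effect phantoms put more mass near nSets than the binomial null", {
  coh <- generateCohort(phantomParams(dims = c(16L, 16L, 16L),
                                      nPerClass = 16L, effectSize = 0.5,
                                      roiSpec = matrix(c(8, 8, 8, 2.5), 1),
                                      noiseSd = 0.1, smoothFwhm = 1,
                                      seed = 13L))
  scheme <- makeSlidingSubsets(16L, 8L, 4L, orderSeed = 3L)   # 3 sets
  cm <- runConsensus(coh, scheme, tau = 0.1, fraction = 0.2)
  obs <- consensusHistogram(cm)
  null <- binomialNull(nSets(cm), 0.2, length(counts(cm)))
  # right-tail excess: unanimous selection far above the independent null
  expect_gt(obs$observed[obs$k == nSets(cm)],
            null$expected[null$k == nSets(cm)])
})
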