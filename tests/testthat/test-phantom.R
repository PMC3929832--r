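test_that("template is brain-like, deterministic and respects dims", {
  tpl <- makeTemplate(c(32L, 32L, 32L))
  d <- volData(tpl)
  expect_gte(d[16, 16, 16], 0.8)        # high-probability core
  expect_identical(d[1, 1, 1], 0)       # zero at the corner
  expect_identical(volData(makeTemplate(c(32L, 32L, 32L))), d)

  tpl2 <- makeTemplate(c(16L, 20L, 16L))
  expect_identical(dim(tpl2), c(16L, 20L, 16L))
  expect_true(all(volData(tpl2) >= 0 & volData(tpl2) <= 1))

  expect_error(makeTemplate(c(4L, 32L, 32L)), "dims")
})

test_that("noiseless cohorts plant the effect exactly", {
  coh <- generateCohort(phantomParams(dims = c(16L, 16L, 16L),
                                      nPerClass = 3L, effectSize = 0.5,
                                      roiSpec = matrix(c(8, 8, 8, 2.5), 1),
                                      noiseSd = 0, seed = 1L))
  vols <- lapply(seq_len(length(coh)), function(i) volData(coh[[i]]))
  mN <- Reduce(`+`, vols[1:3]) / 3
  mA <- Reduce(`+`, vols[4:6]) / 3
  diff <- mN - mA
  tm <- truthMask(coh)
  expect_true(all(abs(diff[tm] - 0.5) < 1e-12))
  expect_true(all(abs(diff[!tm]) < 1e-12))
})

test_that("cohorts are reproducible from the seed and vary across seeds", {
  a <- generateCohort(tinyParams(seed = 7L))
  b <- generateCohort(tinyParams(seed = 7L))
  c <- generateCohort(tinyParams(seed = 8L))
  expect_identical(volData(a[[1]]), volData(b[[1]]))
  expect_identical(volData(a[[8]]), volData(b[[8]]))
  expect_false(identical(volData(a[[1]]), volData(c[[1]])))
  expect_true(all(vapply(seq_len(length(a)), function(i) {
    v <- volData(a[[i]]); min(v) >= 0 && max(v) <= 1
  }, logical(1))))
})

test_that("noise marginal variance matches noiseSd^2 away from clipping", {
  # large n, smoothed noise; template core (0.9) with sd 0.03 never clips
  p <- phantomParams(dims = c(16L, 16L, 16L), nPerClass = 100L,
                     effectSize = 0, roiSpec = matrix(c(8, 8, 8, 2), 1),
                     noiseSd = 0.03, smoothFwhm = 2, seed = 3L)
  coh <- generateCohort(p)
  core <- volData(makeTemplate(p@dims)) >= 0.89
  vals <- sapply(seq_len(length(coh)), function(i) volData(coh[[i]])[core])
  v <- apply(vals, 1, var)          # per-voxel variance across 200 subjects
  expect_lt(abs(mean(v) - 0.03^2) / 0.03^2, 0.10)
})

test_that("null phantom t-test rejects at about the nominal rate", {
  coh <- generateCohort(phantomParams(dims = c(22L, 22L, 22L),
                                      nPerClass = 30L, effectSize = 0,
                                      noiseSd = 0.1, smoothFwhm = 0,
                                      seed = 11L))
  fm <- buildFeatureMatrix(coh)
  sel <- ttestSelect(fm, mode = "p_threshold", alphaOrFraction = 0.05)
  rate <- length(featureIndices(sel)) / nFeatures(fm)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("NIfTI round trip preserves data, dims and voxel size", {
  coh <- generateCohort(tinyParams(seed = 2L))
  v <- coh[[1]]
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  v2 <- readVolume(f)
  expect_lte(max(abs(volData(v) - volData(v2))), 1e-6)
  expect_identical(dim(v2), dim(v))
  expect_equal(voxelSize(v2), c(1.5, 1.5, 1.5))
  expect_error(readVolume(file.path(tempdir(), "nope.nii")), "no such")
})

test_that("cohort export writes volumes, params and a manifest", {
  coh <- generateCohort(tinyParams(seed = 3L))
  dir <- withr::local_tempdir()
  mpath <- writeCohort(coh, dir)
  man <- read.csv(mpath)
  expect_equal(nrow(man), 8L)
  expect_setequal(unique(man$label), c("Normal", "AD"))
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(file.exists(file.path(dir, "phantom_params.yaml")))
  expect_true(file.exists(file.path(dir, "truth_mask.nii.gz")))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantomParams(roiSpec = matrix(c(2, 16, 16, 5), 1)),
               "inside dims")
  expect_error(phantomParams(nPerClass = 0L), "nPerClass")
  expect_error(phantomParams(effectSize = 1.2), "effectSize")
})
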