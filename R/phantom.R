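#' @include AllClasses.R utils.R
NULL

#' Construct phantom generator parameters
#'
#' Builds and validates a [PhantomParams-class]. The defaults define a
#' desk-scale phantom: a 32^3 grid with two planted spherical regions of
#' radius 4.5 voxels placed symmetrically about the midline (emulating the
#' bilateral medial-temporal pattern of gray-matter atrophy), 30 subjects
#' per class, an AD probability deficit of 0.4 inside the regions, and
#' spatially correlated noise (sd 0.1, FWHM 3 voxels). The full-resolution
#' 121 x 145 x 121 grid at 1.5 mm is available via `dims`.
#'
#' @param dims integer length-3 grid dims (all >= 8).
#' @param nPerClass subjects per class.
#' @param effectSize mean probability reduction inside the planted regions
#'   for AD subjects, in \[0, 1\].
#' @param roiSpec numeric matrix with columns `cx, cy, cz, radius`
#'   (voxel units); default: two bilateral spheres scaled to `dims`.
#' @param noiseSd marginal standard deviation of the additive noise.
#' @param smoothFwhm FWHM in voxels of the Gaussian spatial correlation of
#'   the noise; 0 gives i.i.d. noise.
#' @param tissue `"GM"` or `"WM"`.
#' @param voxelSize voxel edge lengths in mm.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a validated [PhantomParams-class].
#' @examples
#' p <- phantomParams(nPerClass = 5L, seed = 7L)
#' @export
phantomParams <- function(dims = c(32L, 32L, 32L),
                          nPerClass = 30L,
                          effectSize = 0.4,
                          roiSpec = NULL,
                          noiseSd = 0.1,
                          smoothFwhm = 3,
                          tissue = "GM",
                          voxelSize = c(1.5, 1.5, 1.5),
                          seed = 1L) {
  dims <- as.integer(dims)
  if (is.null(roiSpec)) {
    # two bilateral spheres in the high-probability core, scaled to dims
    c0 <- (dims + 1) / 2
    off <- max(3, round(0.14 * dims[1L]))
    rad <- max(2, 0.14 * min(dims))
    roiSpec <- rbind(
      c(c0[1L] - off, c0[2L], c0[3L], rad),
      c(c0[1L] + off, c0[2L], c0[3L], rad)
    )
  }
  roiSpec <- as.matrix(roiSpec)
  colnames(roiSpec) <- c("cx", "cy", "cz", "radius")
  new("PhantomParams",
      dims = dims, nPerClass = as.integer(nPerClass),
      effectSize = effectSize, roiSpec = roiSpec,
      noiseSd = noiseSd, smoothFwhm = smoothFwhm,
      tissue = tissue, voxelSize = as.numeric(voxelSize),
      seed = as.integer(seed))
}

#' Deterministic brain-like template volume
#'
#' A centered ellipsoid of high tissue probability (0.9 core) with a
#' smooth cosine falloff to exactly 0 at the border, standing in for the
#' class-average output of tissue segmentation. Identical dims and tissue
#' always give a bit-identical volume. The WM template is a smaller
#' ellipsoid than the GM one, mirroring the smaller white-matter extent.
#'
#' @param dims integer length-3, all >= 8.
#' @param tissue `"GM"` (default) or `"WM"`.
#' @param voxelSize voxel size in mm, recorded in the result.
#' @return a [SegmentedVolume-class].
#' @examples
#' tpl <- makeTemplate(c(16L, 20L, 16L))
#' range(volData(tpl))
#' @export
makeTemplate <- function(dims, tissue = "GM", voxelSize = c(1.5, 1.5, 1.5)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 8L))
    stop("dims must be three integers, all >= 8, to contain an ellipsoid")
  if (!tissue %in% .TISSUES) stop("tissue must be 'GM' or 'WM'")
  scale <- if (tissue == "GM") 0.42 else 0.30
  peak <- if (tissue == "GM") 0.9 else 0.85
  ctr <- (dims + 1) / 2
  ax <- scale * dims
  g <- expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                   z = seq_len(dims[3L]))
  rho <- sqrt(((g$x - ctr[1L]) / ax[1L])^2 +
              ((g$y - ctr[2L]) / ax[2L])^2 +
              ((g$z - ctr[3L]) / ax[3L])^2)
  # flat core to rho = 0.7, cosine rolloff to 0 at rho = 1
  p <- numeric(length(rho))
  core <- rho <= 0.7
  edge <- rho > 0.7 & rho < 1
  p[core] <- peak
  p[edge] <- peak * 0.5 * (1 + cos(pi * (rho[edge] - 0.7) / 0.3))
  new("SegmentedVolume", data = array(p, dims),
      voxelSize = as.numeric(voxelSize), tissue = tissue)
}

# Gaussian 1-D kernel from FWHM in voxels, truncated at 4 sigma.
gaussKernel1d <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Convolve a 3-D array with a separable kernel along one axis (zero padding).
convAxis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  a <- aperm(arr, perm)
  da <- dim(a)
  n <- da[1L]
  r <- (length(k) - 1L) / 2L
  band <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    keep <- src >= 1L & src <= n
    band[cbind(idx[keep], src[keep])] <-
      band[cbind(idx[keep], src[keep])] + k[j]
  }
  res <- band %*% matrix(a, n)
  dim(res) <- da
  aperm(res, order(perm))
}

# Smoothed unit-variance Gaussian field: i.i.d. normals convolved with a
# Gaussian kernel, then divided voxelwise by the exact local sd of the
# convolution (sqrt of ones convolved with the squared kernel), so the
# marginal variance is exactly 1 everywhere, edges included.
smoothUnitField <- function(dims, fwhm) {
  z <- array(stats::rnorm(prod(dims)), dims)
  if (fwhm <= 0) return(z)
  k <- gaussKernel1d(fwhm)
  for (ax in 1:3) z <- convAxis(z, k, ax)
  v <- array(1, dims)
  for (ax in 1:3) v <- convAxis(v, k^2, ax)
  z / sqrt(v)
}

# Boolean array of voxels within any planted sphere.
roiTruthMask <- function(dims, roiSpec) {
  m <- array(FALSE, dims)
  if (!nrow(roiSpec)) return(m)
  g <- expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                   z = seq_len(dims[3L]))
  for (i in seq_len(nrow(roiSpec))) {
    d2 <- (g$x - roiSpec[i, 1L])^2 + (g$y - roiSpec[i, 2L])^2 +
          (g$z - roiSpec[i, 3L])^2
    m[d2 <= roiSpec[i, 4L]^2] <- TRUE
  }
  m
}

#' Generate a synthetic phantom cohort with planted regions
#'
#' Each subject's volume is the tissue template plus a spatially smoothed
#' Gaussian noise field (marginal sd `noiseSd`, correlation scale
#' `smoothFwhm`); AD-labeled subjects additionally lose `effectSize` of
#' tissue probability inside the planted truth regions. Values are clipped
#' to \[0, 1\] afterwards. Inter-subject noise is confined to the
#' template's tissue support (voxels with positive template probability):
#' segmentation emits exact zeros outside tissue for every subject, which
#' is what restricts the voxel-as-feature universe to a fraction of the
#' grid (about 27% of the 121 x 145 x 121 grid for gray matter at full
#' scale). The cohort is fully reproducible from `params@seed`; subjects
#' are generated Normal block first, then AD.
#'
#' @param params a [PhantomParams-class] (see [phantomParams()]).
#' @return a [PhantomCohort-class] with ground-truth mask.
#' @examples
#' coh <- generateCohort(phantomParams(nPerClass = 3L, seed = 2L))
#' coh
#' @export
generateCohort <- function(params) {
  stopifnot(is(params, "PhantomParams"))
  validObject(params)
  if (params@nPerClass < 1L) stop("nPerClass must be >= 1")
  dims <- params@dims
  tpl <- volData(makeTemplate(dims, params@tissue, params@voxelSize))
  truth <- roiTruthMask(dims, params@roiSpec)
  n <- params@nPerClass
  labels <- factor(rep(c("Normal", "AD"), each = n),
                   levels = c("Normal", "AD"))
  deficit <- params@effectSize * truth
  support <- tpl > 0
  volumes <- withSeed(params@seed, {
    lapply(seq_len(2L * n), function(i) {
      noise <- if (params@noiseSd > 0)
        params@noiseSd * smoothUnitField(dims, params@smoothFwhm) * support
      else 0
      v <- tpl + noise
      if (labels[i] == "AD") v <- v - deficit
      v <- pmin(pmax(v, 0), 1)
      new("SegmentedVolume", data = array(v, dims),
          voxelSize = params@voxelSize, tissue = params@tissue)
    })
  })
  new("PhantomCohort",
      volumes = volumes, labels = labels,
      subjectIds = sprintf("sub-%03d", seq_len(2L * n)),
      truthMask = truth, params = params)
}

#' Read and write segmented volumes as NIfTI-1
#'
#' `writeVolume()` stores the probability grid and voxel size in a NIfTI-1
#' file; `readVolume()` loads one back. A round trip reproduces the data to
#' float precision and preserves dims and the pixdim header field.
#'
#' @param volume a [SegmentedVolume-class].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tissue tissue tag to attach on read (NIfTI carries none).
#' @return `writeVolume()` the path, invisibly; `readVolume()` a
#'   [SegmentedVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii")
#' writeVolume(makeTemplate(c(12L, 12L, 12L)), f)
#' readVolume(f)
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "SegmentedVolume"))
  img <- RNifti::asNifti(volume@data)
  RNifti::pixdim(img) <- volume@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, tissue = "GM") {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("malformed NIfTI at ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  a <- array(as.numeric(img), dim(img))
  if (length(dim(a)) != 3L)
    stop("malformed NIfTI: field dim must describe a 3-D volume, got ",
         length(dim(a)), " dims")
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("malformed NIfTI: field pixdim must be positive, got ",
         paste(pd, collapse = ", "))
  if (anyNA(a) || min(a) < 0 || max(a) > 1)
    stop("volume values outside [0, 1]; not a tissue-probability map")
  new("SegmentedVolume", data = a, voxelSize = as.numeric(pd),
      tissue = tissue)
}

#' Write a cohort to disk with a manifest
#'
#' Writes one NIfTI per subject plus the truth mask, the generating
#' parameters as YAML, and a CSV manifest (`subject_id`, `label`, `file`).
#'
#' @param cohort a [PhantomCohort-class].
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PhantomCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, paste0(cohort@subjectIds, ".nii.gz"))
  for (i in seq_along(cohort@volumes)) writeVolume(cohort@volumes[[i]], files[i])
  mask <- new("SegmentedVolume", data = array(as.numeric(cohort@truthMask),
                                              dim(cohort@truthMask)),
              voxelSize = cohort@params@voxelSize,
              tissue = cohort@params@tissue)
  writeVolume(mask, file.path(dir, "truth_mask.nii.gz"))
  p <- cohort@params
  yaml::write_yaml(list(
    dims = as.integer(p@dims), n_per_class = p@nPerClass,
    effect_size = p@effectSize, roi_spec = apply(p@roiSpec, 1, as.list),
    noise_sd = p@noiseSd, smoothing_fwhm_vox = p@smoothFwhm,
    tissue = p@tissue, voxel_size_mm = p@voxelSize, seed = p@seed
  ), file.path(dir, "phantom_params.yaml"))
  manifest <- data.frame(subject_id = cohort@subjectIds,
                         label = as.character(cohort@labels),
                         file = basename(files))
  mpath <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
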