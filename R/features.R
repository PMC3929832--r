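#' @include AllClasses.R utils.R
NULL

#' Voxel feature universe of a cohort
#'
#' A voxel enters the feature set when its tissue probability is positive
#' in at least one subject of the cohort, mirroring how classification is
#' restricted to voxels present in the separated tissue segments. Computed
#' once on the full cohort so that feature indices are comparable across
#' all subject subsets.
#'
#' @param cohort a [PhantomCohort-class].
#' @return logical 3-D array, `TRUE` for in-universe voxels.
#' @export
featureUniverse <- function(cohort) {
  stopifnot(is(cohort, "PhantomCohort"), length(cohort) > 0L)
  u <- volData(cohort[[1L]]) > 0
  for (i in seq_len(length(cohort))[-1L]) u <- u | (volData(cohort[[i]]) > 0)
  u
}

#' Build the subjects x voxels feature matrix
#'
#' Flattens each subject's volume over the in-universe voxels into one row
#' of the voxel-as-feature matrix, keeping the 3-D coordinate of every
#' column. Labels are encoded AD = +1, Normal = -1.
#'
#' @param cohort a [PhantomCohort-class].
#' @param universe logical array of in-universe voxels; defaults to
#'   [featureUniverse()] of the cohort.
#' @param subjects integer subject indices to include (default all).
#' @return a [FeatureMatrix-class].
#' @examples
#' coh <- generateCohort(phantomParams(dims = c(8L, 8L, 8L), nPerClass = 3L,
#'                                     roiSpec = matrix(c(4, 4, 4, 1.5), 1)))
#' buildFeatureMatrix(coh)
#' @export
buildFeatureMatrix <- function(cohort, universe = NULL, subjects = NULL) {
  stopifnot(is(cohort, "PhantomCohort"))
  if (is.null(universe)) universe <- featureUniverse(cohort)
  dims <- dim(universe)
  if (is.null(subjects)) subjects <- seq_len(length(cohort))
  sel <- which(universe)
  vmap <- arrayInd(sel, dims)
  storage.mode(vmap) <- "integer"
  X <- matrix(0, length(subjects), length(sel))
  for (r in seq_along(subjects))
    X[r, ] <- volData(cohort[[subjects[r]]])[sel]
  y <- ifelse(cohortLabels(cohort)[subjects] == "AD", 1, -1)
  rownames(X) <- cohort@subjectIds[subjects]
  new("FeatureMatrix", values = X, labels = as.numeric(y),
      voxelMap = vmap, dims = as.integer(dims),
      tissue = cohort@params@tissue)
}

# Restrict a FeatureMatrix to a column subset (keeps the coordinate map).
subsetFeatures <- function(fm, cols) {
  new("FeatureMatrix", values = fm@values[, cols, drop = FALSE],
      labels = fm@labels, voxelMap = fm@voxelMap[cols, , drop = FALSE],
      dims = fm@dims, tissue = fm@tissue)
}

# Render a per-feature numeric vector (ranks, counts, ...) into a volume.
featureVolume <- function(values, voxelMap, dims) {
  vol <- array(0, dims)
  vol[linearIndex(voxelMap, dims)] <- values
  vol
}

#' Export per-feature values as a NIfTI volume
#'
#' Writes elimination ranks, consensus counts or binary masks back into
#' voxel space for inspection in any NIfTI viewer.
#'
#' @param values numeric per-feature vector, or a [SelectionMask-class]
#'   (written as 0/1), or a [ConsensusMap-class] (written as counts).
#' @param path output NIfTI path.
#' @param voxelMap,dims feature coordinates and grid dims (taken from the
#'   object when a mask or consensus map is given).
#' @param voxelSize voxel size in mm for the header.
#' @return the path, invisibly.
#' @export
writeFeatureVolume <- function(values, path, voxelMap = NULL, dims = NULL,
                               voxelSize = c(1.5, 1.5, 1.5)) {
  if (is(values, "SelectionMask")) {
    vol <- array(as.numeric(maskAsVolume(values)), values@dims)
  } else if (is(values, "ConsensusMap")) {
    vol <- featureVolume(as.numeric(values@counts), values@voxelMap,
                         values@dims)
  } else {
    stopifnot(!is.null(voxelMap), !is.null(dims))
    vol <- featureVolume(values, voxelMap, dims)
  }
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}
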