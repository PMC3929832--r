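#' @import methods
NULL

.TISSUES <- c("GM", "WM")
.DUAL_TOL <- 1e-6

#' SegmentedVolume: one subject's tissue-probability grid
#'
#' A 3-D grid of probabilities of belonging to one tissue class (gray or
#' white matter), as produced by MRI tissue segmentation. Values are
#' unitless probabilities in \[0, 1\]; the voxel size is carried in mm.
#'
#' @slot data 3-D numeric array of tissue probabilities in \[0, 1\].
#' @slot voxelSize numeric length-3, voxel edge length in mm per axis.
#' @slot tissue character, `"GM"` or `"WM"`.
#'
#' @seealso [makeTemplate()], [readVolume()], [writeVolume()]
#' @export
setClass("SegmentedVolume",
  representation(
    data = "array",
    voxelSize = "numeric",
    tissue = "character"
  )
)

setValidity("SegmentedVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (anyNA(object@data) || min(object@data) < 0 || max(object@data) > 1)
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive reals (mm)")
  if (length(object@tissue) != 1L || !object@tissue %in% .TISSUES)
    msg <- c(msg, "tissue must be one of 'GM', 'WM'")
  if (length(msg)) msg else TRUE
})

#' PhantomParams: configuration of the synthetic phantom generator
#'
#' Parameters describing a synthetic cohort of segmented volumes with
#' planted discriminative regions. Construct with [phantomParams()], which
#' validates and fills defaults.
#'
#' @slot dims integer length-3 grid dimensions.
#' @slot nPerClass integer, subjects per class (Normal and AD).
#' @slot effectSize numeric in \[0, 1\]: mean probability reduction inside
#'   the planted regions for the AD class.
#' @slot roiSpec numeric matrix with columns `cx, cy, cz, radius` (voxels),
#'   one planted spherical region per row.
#' @slot noiseSd nonnegative numeric, marginal sd of the additive noise.
#' @slot smoothFwhm nonnegative numeric, FWHM (voxels) of the Gaussian
#'   spatial correlation of the noise; 0 means i.i.d. noise.
#' @slot tissue character tissue class of the generated volumes.
#' @slot voxelSize numeric length-3, mm.
#' @slot seed integer RNG seed for the cohort.
#'
#' @export
setClass("PhantomParams",
  representation(
    dims = "integer",
    nPerClass = "integer",
    effectSize = "numeric",
    roiSpec = "matrix",
    noiseSd = "numeric",
    smoothFwhm = "numeric",
    tissue = "character",
    voxelSize = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomParams", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 8L))
    msg <- c(msg, "dims must be three integers, all >= 8")
  if (object@nPerClass < 1L)
    msg <- c(msg, "nPerClass must be >= 1")
  if (object@effectSize < 0 || object@effectSize > 1)
    msg <- c(msg, "effectSize must lie in [0, 1]")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be nonnegative")
  if (object@smoothFwhm < 0)
    msg <- c(msg, "smoothFwhm must be nonnegative")
  if (ncol(object@roiSpec) != 4L)
    msg <- c(msg, "roiSpec must have columns cx, cy, cz, radius")
  if (nrow(object@roiSpec)) {
    ctr <- object@roiSpec[, 1:3, drop = FALSE]
    rad <- object@roiSpec[, 4]
    lo <- ctr - rad   # rad recycles down rows: one radius per ROI
    hi <- ctr + rad
    inside <- all(lo >= 1) &&
      all(hi <= matrix(object@dims, nrow(ctr), 3, byrow = TRUE))
    if (!inside) msg <- c(msg, "every planted ROI must lie fully inside dims")
    if (any(rad <= 0)) msg <- c(msg, "ROI radii must be positive")
  }
  if (!object@tissue %in% .TISSUES)
    msg <- c(msg, "tissue must be 'GM' or 'WM'")
  if (length(msg)) msg else TRUE
})

#' PhantomCohort: a synthetic cohort with ground truth
#'
#' A list of subject volumes with class labels, unique subject identifiers,
#' the boolean truth mask of planted discriminative voxels, and the
#' generating parameters.
#'
#' @slot volumes list of [SegmentedVolume-class], one per subject.
#' @slot labels factor with levels `Normal`, `AD`.
#' @slot subjectIds character vector of unique identifiers.
#' @slot truthMask logical 3-D array marking planted voxels.
#' @slot params the generating [PhantomParams-class].
#'
#' @seealso [generateCohort()]
#' @export
setClass("PhantomCohort",
  representation(
    volumes = "list",
    labels = "factor",
    subjectIds = "character",
    truthMask = "array",
    params = "PhantomParams"
  )
)

setValidity("PhantomCohort", function(object) {
  msg <- character()
  n <- length(object@volumes)
  if (length(object@labels) != n || length(object@subjectIds) != n)
    msg <- c(msg, "volumes, labels and subjectIds must have equal length")
  if (anyDuplicated(object@subjectIds))
    msg <- c(msg, "subjectIds must be unique")
  if (!identical(levels(object@labels), c("Normal", "AD")))
    msg <- c(msg, "labels must be a factor with levels Normal, AD")
  if (n) {
    d0 <- dim(object@volumes[[1]]@data)
    same <- vapply(object@volumes, function(v)
      identical(dim(v@data), d0) &&
        identical(v@voxelSize, object@volumes[[1]]@voxelSize),
      logical(1))
    if (!all(same))
      msg <- c(msg, "all volumes must share dims and voxelSize")
    if (!identical(dim(object@truthMask), d0))
      msg <- c(msg, "truthMask must have the same dims as the volumes")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: subjects x voxel-features with a coordinate map
#'
#' The voxel-as-feature (VAF) representation: one row per subject, one
#' column per in-mask voxel, plus the integer 3-D coordinate of every
#' feature so selections can be rendered back into volumes.
#'
#' @slot values numeric matrix, subjects x M tissue probabilities.
#' @slot labels numeric vector of +1 (AD) / -1 (Normal), one per row.
#' @slot voxelMap integer M x 3 matrix of voxel coordinates (1-based).
#' @slot dims integer length-3 dims of the source volumes.
#' @slot tissue character tissue class.
#'
#' @seealso [buildFeatureMatrix()]
#' @export
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    labels = "numeric",
    voxelMap = "matrix",
    dims = "integer",
    tissue = "character"
  )
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@values))
    msg <- c(msg, "one label per subject row is required")
  if (!all(object@labels %in% c(-1, 1)))
    msg <- c(msg, "labels must be +1 (AD) or -1 (Normal)")
  if (nrow(object@voxelMap) != ncol(object@values))
    msg <- c(msg, "voxelMap must have one entry per feature")
  if (ncol(object@values)) {
    lin <- linearIndex(object@voxelMap, object@dims)
    if (anyDuplicated(lin)) msg <- c(msg, "voxelMap entries must be distinct")
  }
  if (length(msg)) msg else TRUE
})

#' LinearSVMModel: a trained soft-margin hyperplane
#'
#' The maximal-margin hyperplane g(x) = w'x + b for one feature subset,
#' with the dual coefficients it was recovered from. The weight vector
#' satisfies w = sum_i y_i lambda_i x_i over the support vectors, and the
#' duals satisfy 0 <= lambda_i <= C and sum_i y_i lambda_i = 0.
#'
#' @slot w numeric weight vector, length M.
#' @slot b numeric threshold.
#' @slot C positive misclassification penalty used in training.
#' @slot duals numeric vector of Lagrange multipliers, one per training
#'   sample (zero off the support).
#' @slot supportIndices integer indices of samples with positive duals.
#'
#' @seealso [trainLinearSVM()], [decisionFunction()], [weightFromDuals()]
#' @export
setClass("LinearSVMModel",
  representation(
    w = "numeric",
    b = "numeric",
    C = "numeric",
    duals = "numeric",
    supportIndices = "integer"
  )
)

setValidity("LinearSVMModel", function(object) {
  msg <- character()
  if (object@C <= 0) msg <- c(msg, "C must be positive")
  if (any(object@duals < -.DUAL_TOL) ||
      any(object@duals > object@C + .DUAL_TOL))
    msg <- c(msg, "duals must satisfy 0 <= lambda_i <= C")
  if (length(msg)) msg else TRUE
})

#' RFEResult: elimination ranks and the per-loop accuracy trace
#'
#' Output of [svmRFE()]. `eliminationRank` assigns 1 to the first feature
#' discarded; surviving features take the top ranks ordered by their final
#' |w_n|. `loopTrace` records, per loop, the number of features retained
#' and (when evaluated) the leave-10-out accuracy mean and sd.
#'
#' @slot eliminationRank integer vector, length M, a permutation of 1..M.
#' @slot loopTrace data.frame with columns `loop`, `retained`,
#'   `accuracy_mean`, `accuracy_sd` (accuracies in percent, NA when the
#'   per-loop evaluation was skipped).
#' @slot tau integer, features eliminated per loop.
#' @slot C numeric SVM penalty used.
#'
#' @export
setClass("RFEResult",
  representation(
    eliminationRank = "integer",
    loopTrace = "data.frame",
    tau = "integer",
    C = "numeric"
  )
)

setValidity("RFEResult", function(object) {
  msg <- character()
  M <- length(object@eliminationRank)
  if (!identical(sort(object@eliminationRank), seq_len(M)))
    msg <- c(msg, "eliminationRank must be a permutation of 1..M")
  ret <- object@loopTrace$retained
  if (length(ret) > 1 && any(diff(ret) >= 0))
    msg <- c(msg, "features retained must be strictly decreasing")
  if (length(msg)) msg else TRUE
})

#' SubsetScheme: sliding-window subject subsets
#'
#' Overlapping subject subsets built per class by sliding a window of
#' `window` subjects in steps of `window - overlap` over a random subject
#' order, keeping full windows only.
#'
#' @slot window integer, subjects per class per subset.
#' @slot overlap integer, subjects shared by consecutive subsets per class.
#' @slot subsets list of length nSets; each element is a list with integer
#'   vectors `normal` and `ad` of subject indices.
#' @slot nSets integer number of subsets.
#' @slot orderSeed integer seed of the one-off subject shuffle.
#'
#' @seealso [makeSlidingSubsets()]
#' @export
setClass("SubsetScheme",
  representation(
    window = "integer",
    overlap = "integer",
    subsets = "list",
    nSets = "integer",
    orderSeed = "integer"
  )
)

setValidity("SubsetScheme", function(object) {
  msg <- character()
  if (object@overlap < 0L || object@overlap >= object@window)
    msg <- c(msg, "overlap must satisfy 0 <= overlap < window")
  if (length(object@subsets) != object@nSets)
    msg <- c(msg, "nSets must equal the number of subsets")
  ok <- vapply(object@subsets, function(s)
    length(s$normal) == object@window && length(s$ad) == object@window,
    logical(1))
  if (!all(ok))
    msg <- c(msg, "every subset must hold exactly `window` subjects per class")
  if (object@nSets > 1L) {
    for (k in seq_len(object@nSets - 1L)) {
      sh <- length(intersect(object@subsets[[k]]$normal,
                             object@subsets[[k + 1L]]$normal))
      if (sh != object@overlap)
        msg <- c(msg, "consecutive subsets must share exactly `overlap` subjects")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' ConsensusMap: per-feature selection counts across subsets
#'
#' For every feature, the number of subject subsets whose top-fraction
#' SVM-RFE selection included it.
#'
#' @slot counts integer vector, length M, each in \[0, nSets\].
#' @slot nSets integer number of subsets counted.
#' @slot fraction numeric, the selected top fraction (default 0.2).
#' @slot voxelMap integer M x 3 feature coordinates.
#' @slot dims integer length-3 volume dims.
#'
#' @seealso [runConsensus()], [thresholdConsensus()], [binomialNull()]
#' @export
setClass("ConsensusMap",
  representation(
    counts = "integer",
    nSets = "integer",
    fraction = "numeric",
    voxelMap = "matrix",
    dims = "integer"
  )
)

setValidity("ConsensusMap", function(object) {
  msg <- character()
  if (any(object@counts < 0L) || any(object@counts > object@nSets))
    msg <- c(msg, "counts must lie in [0, nSets]")
  if (object@fraction <= 0 || object@fraction > 1)
    msg <- c(msg, "fraction must lie in (0, 1]")
  M <- length(object@counts)
  if (sum(object@counts > 0L) >
      object@nSets * ceiling(object@fraction * M))
    msg <- c(msg, "more nonzero counts than nSets * ceil(fraction * M)")
  if (length(msg)) msg else TRUE
})

#' SelectionMask: a set of selected voxel features
#'
#' @slot featureIndices integer feature (column) indices, unique, 1-based.
#' @slot voxelMap integer M x 3 coordinates of the full feature universe.
#' @slot dims integer length-3 volume dims.
#'
#' @seealso [selectTopFraction()], [ttestSelect()], [maskAsVolume()]
#' @export
setClass("SelectionMask",
  representation(
    featureIndices = "integer",
    voxelMap = "matrix",
    dims = "integer"
  )
)

setValidity("SelectionMask", function(object) {
  msg <- character()
  idx <- object@featureIndices
  if (anyDuplicated(idx)) msg <- c(msg, "featureIndices must be unique")
  if (length(idx) && (min(idx) < 1L || max(idx) > nrow(object@voxelMap)))
    msg <- c(msg, "featureIndices out of range of the feature universe")
  if (length(msg)) msg else TRUE
})

#' EvalReport: cross-validated accuracy of one classification task
#'
#' @slot accuracyPct numeric overall accuracy in percent.
#' @slot foldAccuracies numeric per-fold accuracies in percent.
#' @slot nFolds integer number of 10-sample test groups.
#' @slot selector character, which selector produced the feature set.
#' @slot nFeaturesUsed integer features entering the classifier.
#' @slot foldSeed integer seed of the fold assignment.
#'
#' @seealso [leave10outAccuracy()]
#' @export
setClass("EvalReport",
  representation(
    accuracyPct = "numeric",
    foldAccuracies = "numeric",
    nFolds = "integer",
    selector = "character",
    nFeaturesUsed = "integer",
    foldSeed = "integer"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (object@nFolds != length(object@foldAccuracies))
    msg <- c(msg, "nFolds must match the number of fold accuracies")
  if (length(object@foldAccuracies) &&
      abs(object@accuracyPct - mean(object@foldAccuracies)) > 1e-9)
    msg <- c(msg, "accuracyPct must equal the mean of foldAccuracies")
  if (!object@selector %in% c("svm_rfe", "ttest_p", "ttest_top20", "none"))
    msg <- c(msg, "unknown selector tag")
  if (length(msg)) msg else TRUE
})
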