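#' @include AllClasses.R
NULL

#' Accessors for voxelRFE objects
#'
#' Small accessor generics for the package's S4 containers: `volData()`
#' (the 3-D probability array), `voxelSize()` (mm), `tissueType()`,
#' `truthMask()`, `cohortLabels()`, `featureValues()`, `featureLabels()`,
#' `voxelMap()`, `nFeatures()`, `weights()`, `bias()`, `duals()`,
#' `supportIndices()`, `eliminationRank()`, `loopTrace()`, `counts()`,
#' `nSets()`, `featureIndices()`, `accuracy()` and `foldAccuracies()`.
#'
#' @param object a voxelRFE S4 object.
#' @return The slot value the accessor names.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(object) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("tissueType", function(object) standardGeneric("tissueType"))
#' @rdname accessors
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))
#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(object) standardGeneric("cohortLabels"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))
#' @rdname accessors
#' @export
setGeneric("voxelMap", function(object) standardGeneric("voxelMap"))
#' @rdname accessors
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))
#' @rdname accessors
#' @export
setGeneric("weights", function(object) standardGeneric("weights"))
#' @rdname accessors
#' @export
setGeneric("bias", function(object) standardGeneric("bias"))
#' @rdname accessors
#' @export
setGeneric("duals", function(object) standardGeneric("duals"))
#' @rdname accessors
#' @export
setGeneric("supportIndices", function(object) standardGeneric("supportIndices"))
#' @rdname accessors
#' @export
setGeneric("eliminationRank", function(object) standardGeneric("eliminationRank"))
#' @rdname accessors
#' @export
setGeneric("loopTrace", function(object) standardGeneric("loopTrace"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("nSets", function(object) standardGeneric("nSets"))
#' @rdname accessors
#' @export
setGeneric("featureIndices", function(object) standardGeneric("featureIndices"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(object) standardGeneric("foldAccuracies"))

setMethod("volData", "SegmentedVolume", function(object) object@data)
setMethod("voxelSize", "SegmentedVolume", function(object) object@voxelSize)
setMethod("tissueType", "SegmentedVolume", function(object) object@tissue)
setMethod("dim", "SegmentedVolume", function(x) dim(x@data))

setMethod("truthMask", "PhantomCohort", function(object) object@truthMask)
setMethod("cohortLabels", "PhantomCohort", function(object) object@labels)
setMethod("length", "PhantomCohort", function(x) length(x@volumes))
setMethod("[[", "PhantomCohort", function(x, i) x@volumes[[i]])

setMethod("featureValues", "FeatureMatrix", function(object) object@values)
setMethod("featureLabels", "FeatureMatrix", function(object) object@labels)
setMethod("voxelMap", "FeatureMatrix", function(object) object@voxelMap)
setMethod("nFeatures", "FeatureMatrix", function(object) ncol(object@values))
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("weights", "LinearSVMModel", function(object) object@w)
setMethod("bias", "LinearSVMModel", function(object) object@b)
setMethod("duals", "LinearSVMModel", function(object) object@duals)
setMethod("supportIndices", "LinearSVMModel",
          function(object) object@supportIndices)

setMethod("eliminationRank", "RFEResult", function(object) object@eliminationRank)
setMethod("loopTrace", "RFEResult", function(object) object@loopTrace)

setMethod("counts", "ConsensusMap", function(object) object@counts)
setMethod("nSets", "ConsensusMap", function(object) object@nSets)
setMethod("voxelMap", "ConsensusMap", function(object) object@voxelMap)

setMethod("featureIndices", "SelectionMask", function(object) object@featureIndices)
setMethod("voxelMap", "SelectionMask", function(object) object@voxelMap)
setMethod("length", "SelectionMask", function(x) length(x@featureIndices))

setMethod("nSets", "SubsetScheme", function(object) object@nSets)
setMethod("length", "SubsetScheme", function(x) x@nSets)
setMethod("[[", "SubsetScheme", function(x, i) x@subsets[[i]])

setMethod("accuracy", "EvalReport", function(object) object@accuracyPct)
setMethod("foldAccuracies", "EvalReport", function(object) object@foldAccuracies)

setMethod("show", "SegmentedVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("SegmentedVolume [%s] %d x %d x %d, voxel %s mm, range [%.3f, %.3f]\n",
              object@tissue, d[1], d[2], d[3],
              paste(format(object@voxelSize), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "PhantomCohort", function(object) {
  cat(sprintf("PhantomCohort: %d subjects (%d Normal, %d AD), dims %s, %d truth voxels\n",
              length(object@volumes),
              sum(object@labels == "Normal"), sum(object@labels == "AD"),
              paste(dim(object@truthMask), collapse = " x "),
              sum(object@truthMask)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d subjects x %d voxel features (dims %s)\n",
              object@tissue, nrow(object@values), ncol(object@values),
              paste(object@dims, collapse = " x ")))
})

setMethod("show", "LinearSVMModel", function(object) {
  cat(sprintf("LinearSVMModel: M = %d, C = %g, %d support vectors, |b| = %.4g\n",
              length(object@w), object@C, length(object@supportIndices),
              abs(object@b)))
})

setMethod("show", "RFEResult", function(object) {
  cat(sprintf("RFEResult: M = %d features, tau = %d, %d loops, C = %g\n",
              length(object@eliminationRank), object@tau,
              nrow(object@loopTrace), object@C))
})

setMethod("show", "SubsetScheme", function(object) {
  cat(sprintf("SubsetScheme: %d sets, window %d/class, overlap %d (seed %d)\n",
              object@nSets, object@window, object@overlap, object@orderSeed))
})

setMethod("show", "ConsensusMap", function(object) {
  cat(sprintf("ConsensusMap: %d features, %d sets, top %.0f%%; counts in [%d, %d]\n",
              length(object@counts), object@nSets, 100 * object@fraction,
              min(object@counts), max(object@counts)))
})

setMethod("show", "SelectionMask", function(object) {
  cat(sprintf("SelectionMask: %d of %d features selected\n",
              length(object@featureIndices), nrow(object@voxelMap)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s]: %.2f%% accuracy over %d folds, %d features\n",
              object@selector, object@accuracyPct, object@nFolds,
              object@nFeaturesUsed))
})
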