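#' @include rfe.R features.R
NULL

#' Sliding-window subject subsets
#'
#' Shuffles the subjects of each class once (seeded), then slides a window
#' of `window` subjects per class in steps of `window - overlap`, keeping
#' full windows only, so that nSets = floor((nPerClass - window) /
#' (window - overlap)) + 1. With 185 subjects per class, window 30 and
#' overlap 25 this yields the 32-set design.
#'
#' @param nPerClass subjects available per class.
#' @param window subjects per class per subset.
#' @param overlap subjects shared by consecutive subsets per class.
#' @param orderSeed seed of the one-off subject shuffle.
#' @return a [SubsetScheme-class]. Index lists refer to positions 1..N per
#'   class; `normal` entries index the Normal block, `ad` the AD block of
#'   a cohort generated Normal-first.
#' @examples
#' nSets(makeSlidingSubsets(185L, 30L, 25L))   # 32
#' @export
makeSlidingSubsets <- function(nPerClass, window = 30L, overlap = 25L,
                               orderSeed = 1L) {
  nPerClass <- as.integer(nPerClass)
  window <- as.integer(window); overlap <- as.integer(overlap)
  if (window > nPerClass)
    stop("window (", window, ") exceeds subjects per class (", nPerClass, ")")
  if (overlap < 0L || overlap >= window)
    stop("overlap must satisfy 0 <= overlap < window")
  step <- window - overlap
  nSets <- (nPerClass - window) %/% step + 1L
  ordN <- withSeed(orderSeed, sample(nPerClass))
  ordA <- withSeed(childSeed(orderSeed, 1L), sample(nPerClass))
  subsets <- lapply(seq_len(nSets), function(k) {
    at <- (k - 1L) * step + seq_len(window)
    list(normal = ordN[at], ad = nPerClass + ordA[at])
  })
  new("SubsetScheme", window = window, overlap = overlap,
      subsets = subsets, nSets = nSets, orderSeed = as.integer(orderSeed))
}

#' Consensus selection counts across sliding-window subsets
#'
#' Runs SVM-RFE independently on every subject subset, takes each
#' subset's top-`fraction` most-relevant features, and counts per feature
#' how many subsets selected it. The feature universe is fixed once on
#' the full cohort so counts are comparable across subsets. Selection
#' repeated over overlapping sets quantifies how far the discovered
#' regions generalize: features selected by many sets are stable regions
#' of interest, features selected by few are subset idiosyncrasies.
#'
#' @param cohort a [PhantomCohort-class].
#' @param scheme a [SubsetScheme-class] consistent with the cohort size.
#' @param C,tau see [svmRFE()].
#' @param fraction top fraction selected per subset (default 0.2).
#' @param universe optional precomputed [featureUniverse()] array.
#' @param evalFolds per-loop CV seed passed to [svmRFE()], or `NULL`
#'   (default) to skip per-loop evaluation.
#' @return a [ConsensusMap-class].
#' @export
runConsensus <- function(cohort, scheme, C = 1, tau = 0.04, fraction = 0.2,
                         universe = NULL, evalFolds = NULL) {
  stopifnot(is(cohort, "PhantomCohort"), is(scheme, "SubsetScheme"))
  nPerClass <- sum(cohortLabels(cohort) == "Normal")
  if (scheme@window > nPerClass)
    stop("scheme window exceeds cohort size per class")
  if (is.null(universe)) universe <- featureUniverse(cohort)
  fm0 <- buildFeatureMatrix(cohort, universe,
                            c(scheme@subsets[[1L]]$normal,
                              scheme@subsets[[1L]]$ad))
  M <- nFeatures(fm0)
  cnt <- integer(M)
  for (k in seq_len(scheme@nSets)) {
    fm <- if (k == 1L) fm0 else {
      sub <- scheme@subsets[[k]]
      buildFeatureMatrix(cohort, universe, c(sub$normal, sub$ad))
    }
    res <- svmRFE(fm, C = C, tau = tau,
                  evalFolds = if (is.null(evalFolds)) NULL
                              else childSeed(evalFolds, k))
    mask <- selectTopFraction(res, fraction, fm@voxelMap, fm@dims)
    cnt[featureIndices(mask)] <- cnt[featureIndices(mask)] + 1L
  }
  new("ConsensusMap", counts = cnt, nSets = scheme@nSets,
      fraction = fraction, voxelMap = fm0@voxelMap, dims = fm0@dims)
}

#' Binomial null reference for consensus counts
#'
#' If every subset selected its top fraction independently and uniformly
#' at random, the number of sets selecting a given feature would follow
#' Binomial(nSets, p). This returns the expected count histogram
#' M * PMF(k; nSets, p) for k = 0..nSets — the reference curve against
#' which the observed consensus histogram is displayed. Real consensus
#' deviates from it: stable discriminative voxels produce right-tail
#' excess. No inferential test is attached; overlapping subsets make the
#' counts dependent, so the curve is descriptive only.
#'
#' @param nSets number of subsets (e.g. 32).
#' @param p per-set selection probability (the top fraction, e.g. 0.2).
#' @param M number of features.
#' @return data.frame with columns `k`, `pmf`, `expected` (= M * pmf).
#' @examples
#' h <- binomialNull(32, 0.2, 1000)
#' sum(h$pmf); sum(h$k * h$pmf)   # 1 and n*p = 6.4
#' @export
binomialNull <- function(nSets, p, M = 1) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (nSets < 1L) stop("nSets must be >= 1")
  k <- 0:nSets
  pmf <- stats::dbinom(k, nSets, p)
  data.frame(k = k, pmf = pmf, expected = M * pmf)
}

#' Threshold a consensus map into a selection mask
#'
#' Keeps the features selected by at least `minSets` subsets. The
#' operating points used for reporting are fractions 0.44, 0.56, 0.75 and
#' 1.0 of the sets; the 0.75 masks are the exported robust ROI volumes.
#'
#' @param map a [ConsensusMap-class].
#' @param minSets integer in \[0, nSets\].
#' @return a [SelectionMask-class].
#' @examples
#' # counts 5, 20, 31 of 32 sets at the 75% threshold: only the third stays
#' @export
thresholdConsensus <- function(map, minSets) {
  stopifnot(is(map, "ConsensusMap"))
  if (minSets < 0 || minSets > map@nSets)
    stop("minSets must lie in [0, nSets]")
  new("SelectionMask",
      featureIndices = which(map@counts >= minSets),
      voxelMap = map@voxelMap, dims = map@dims)
}

#' Observed consensus count histogram
#'
#' Tabulates how many features were selected by exactly k subsets,
#' k = 0..nSets, for comparison with [binomialNull()].
#'
#' @param map a [ConsensusMap-class].
#' @return data.frame with columns `k` and `observed`.
#' @export
consensusHistogram <- function(map) {
  stopifnot(is(map, "ConsensusMap"))
  k <- 0:map@nSets
  data.frame(k = k,
             observed = as.integer(tabulate(map@counts + 1L,
                                            nbins = map@nSets + 1L)))
}
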