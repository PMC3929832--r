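#' @include svm.R stats_eval.R
NULL

#' SVM recursive feature elimination
#'
#' The wrapper loop: (1) train the ranking SVM on all samples restricted
#' to the surviving features; (2) sort surviving features by |w_n|
#' ascending — features with |w_n| near 0 do not contribute to g(x); (3)
#' assign elimination ranks to the `tau` lowest and discard them (never
#' discarding below one surviving feature); (4) optionally evaluate a
#' fresh SVM on the surviving set by leave-10-out cross-validation;
#' repeat until a single feature remains. The ranking SVM is deliberately
#' trained on all samples of the subset — the selection-bias caveat that
#' entails is inherited by design and quantified elsewhere via the
#' multi-subset consensus scheme.
#'
#' Ties in |w_n| are broken by eliminating the lower voxel linear index
#' first, so the procedure is fully deterministic.
#'
#' @param X a [FeatureMatrix-class] or numeric samples x M matrix.
#' @param y numeric labels in \{-1, +1\} (taken from `X` when omitted).
#' @param C soft-margin penalty.
#' @param tau features eliminated per loop. An integer `tau >= 1` is an
#'   absolute count; a fractional `0 < tau < 1` is converted to
#'   `max(1, round(tau * M))`. Default 0.04 (4% of M, matching the
#'   elimination step used at full scale, ~3.5-4% of the features).
#' @param evalFolds seed for the per-loop leave-10-out evaluation, or
#'   `NULL` to skip it (the trace then carries NA accuracies).
#' @return an [RFEResult-class].
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(20 * 4), 20)
#' y <- rep(c(-1, 1), each = 10)
#' X[, 1] <- X[, 1] + y          # one informative feature
#' svmRFE(X, y, tau = 1)
#' @export
svmRFE <- function(X, y = NULL, C = 1, tau = 0.04, evalFolds = NULL) {
  vmap <- NULL
  if (is(X, "FeatureMatrix")) {
    if (is.null(y)) y <- X@labels
    vmap <- linearIndex(X@voxelMap, X@dims)
    X <- X@values
  }
  X <- as.matrix(X)
  M <- ncol(X)
  if (M < 1L) stop("at least one feature is required")
  if (is.null(vmap)) vmap <- seq_len(M)
  if (tau <= 0) stop("tau must be positive")
  tau <- if (tau < 1) max(1L, as.integer(round(tau * M))) else as.integer(tau)
  if (tau >= M)
    warning("tau >= number of features; elimination completes in one loop")

  evalAcc <- function(cols) {
    if (is.null(evalFolds) || length(y) < 20L) return(c(NA_real_, NA_real_))
    rep_ <- leave10outAccuracy(X[, cols, drop = FALSE], y, C = C,
                               foldSeed = evalFolds, selector = "svm_rfe")
    c(rep_@accuracyPct, stats::sd(rep_@foldAccuracies))
  }

  rank <- integer(M)
  surviving <- seq_len(M)
  nextRank <- 1L
  a0 <- evalAcc(surviving)
  trace <- list(data.frame(loop = 0L, retained = M,
                           accuracy_mean = a0[1L], accuracy_sd = a0[2L]))
  loop <- 0L
  while (length(surviving) > 1L) {
    loop <- loop + 1L
    fit <- trainLinearSVM(X[, surviving, drop = FALSE], y, C = C)
    aw <- abs(fit@w)
    ord <- order(aw, vmap[surviving])           # ties: lower voxel index first
    k <- min(tau, length(surviving) - 1L)
    drop_ <- ord[seq_len(k)]
    rank[surviving[drop_]] <- nextRank + seq_len(k) - 1L
    nextRank <- nextRank + k
    if (length(surviving) - k == 1L) {
      # final survivor takes the top rank by its final |w| ordering
      rank[surviving[ord[k + 1L]]] <- nextRank
      nextRank <- nextRank + 1L
      surviving <- surviving[-drop_]
      a <- evalAcc(surviving)
      trace[[length(trace) + 1L]] <-
        data.frame(loop = loop, retained = length(surviving),
                   accuracy_mean = a[1L], accuracy_sd = a[2L])
      break
    }
    surviving <- surviving[-drop_]
    a <- evalAcc(surviving)
    trace[[length(trace) + 1L]] <-
      data.frame(loop = loop, retained = length(surviving),
                 accuracy_mean = a[1L], accuracy_sd = a[2L])
  }
  if (M == 1L) rank[1L] <- 1L
  new(Class = "RFEResult", eliminationRank = rank,
      loopTrace = do.call(rbind, trace),
      tau = tau, C = C)
}

#' Select the top fraction of RFE-ranked features
#'
#' Returns the `ceiling(fraction * M)` features with the highest
#' elimination rank — those discarded last or never discarded. The default
#' operating point keeps the top 20% most-relevant features as regions of
#' interest.
#'
#' @param result an [RFEResult-class].
#' @param fraction in (0, 1\].
#' @param voxelMap,dims feature coordinates and grid dims for rendering
#'   the mask (defaults to the feature index line when omitted).
#' @return a [SelectionMask-class].
#' @export
selectTopFraction <- function(result, fraction = 0.2,
                              voxelMap = NULL, dims = NULL) {
  stopifnot(is(result, "RFEResult"))
  M <- length(result@eliminationRank)
  if (M < 1L) stop("empty RFE result")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  k <- as.integer(ceiling(fraction * M))
  idx <- which(result@eliminationRank > M - k)
  if (is.null(voxelMap)) {
    voxelMap <- cbind(seq_len(M), 1L, 1L)
    storage.mode(voxelMap) <- "integer"
    dims <- c(M, 1L, 1L)
  }
  new("SelectionMask", featureIndices = as.integer(idx),
      voxelMap = voxelMap, dims = as.integer(dims))
}
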