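#' @include svm.R features.R
NULL

#' Leave-10-out cross-validated accuracy
#'
#' The evaluation scheme used throughout: all samples train the classifier
#' except a held-out group of exactly 10, repeated S = floor(N/10) times
#' over disjoint, class-stratified groups; the reported accuracy is the
#' percentage of correctly classified held-out subjects. For N = 60 this
#' is 6 folds. (This "10-fold" holds 10 *subjects* out per fold — not the
#' standard tenth-of-the-data fold.) Samples beyond the first 10*S after
#' the seeded shuffle are never tested (they still serve as training
#' data).
#'
#' @param X a [FeatureMatrix-class] or samples x M numeric matrix.
#' @param y labels in \{-1, +1\} (taken from `X` when omitted).
#' @param C soft-margin penalty.
#' @param foldSeed integer seed of the stratified fold shuffle.
#' @param selector tag recorded in the report.
#' @return an [EvalReport-class].
#' @examples
#' set.seed(4)
#' X <- matrix(rnorm(40 * 3), 40); y <- rep(c(-1, 1), 20)
#' X[, 2] <- X[, 2] + 2 * y
#' accuracy(leave10outAccuracy(X, y, foldSeed = 9L))
#' @export
leave10outAccuracy <- function(X, y = NULL, C = 1, foldSeed = 1L,
                               selector = "none") {
  if (is(X, "FeatureMatrix")) {
    if (is.null(y)) y <- X@labels
    X <- X@values
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 20L) stop("need at least 20 samples for leave-10-out CV")
  S <- n %/% 10L
  folds <- stratifiedFolds(y, S, foldSeed)
  foldAcc <- numeric(S)
  for (s in seq_len(S)) {
    test <- folds[[s]]
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2L)
      stop("a training fold lost one class entirely; stratification impossible")
    fit <- trainLinearSVM(X[train, , drop = FALSE], y[train], C = C)
    pred <- sign(decisionFunction(fit, X[test, , drop = FALSE]))
    pred[pred == 0] <- 1
    foldAcc[s] <- 100 * mean(pred == y[test])
  }
  new("EvalReport", accuracyPct = mean(foldAcc), foldAccuracies = foldAcc,
      nFolds = as.integer(S), selector = selector,
      nFeaturesUsed = ncol(X), foldSeed = as.integer(foldSeed))
}

# Disjoint stratified groups of exactly 10 samples. Classes are shuffled
# independently, interleaved in proportion, and dealt into S groups.
stratifiedFolds <- function(y, S, seed) {
  idx <- withSeed(seed, {
    classes <- unique(y)
    pools <- lapply(classes, function(cl) sample(which(y == cl)))
    # deal class members round-robin across folds to balance them
    folds <- vector("list", S)
    slots <- rep(0L, S)
    for (p in pools) {
      for (i in seq_along(p)) {
        open <- which(slots < 10L)
        if (!length(open)) break
        f <- open[1L + (i - 1L) %% length(open)]
        folds[[f]] <- c(folds[[f]], p[i])
        slots[f] <- slots[f] + 1L
      }
    }
    folds
  })
  idx
}

#' Voxelwise two-sample Student's t statistic
#'
#' Pooled-variance (equal-variance) two-sided t test for independent
#' samples with df = n_a + n_b - 2, the baseline voxelwise contrast at
#' significance level p = 0.05. When the pooled variance is zero the t
#' statistic is undefined and the result is flagged degenerate; a zero
#' mean difference is then reported non-significant (p = 1), a nonzero
#' one as infinite separation (p = 0).
#'
#' @param a,b numeric vectors (one group each, >= 2 samples).
#' @return list with `t`, `p`, `df`, `degenerate`.
#' @examples
#' ttestStatistic(c(1, 2, 3), c(4, 5, 6))
#' @export
ttestStatistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 <= 0) {
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) NA_real_ else sign(d) * Inf,
                p = if (d == 0) 1 else 0, df = df, degenerate = TRUE))
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, degenerate = FALSE)
}

# Vectorized pooled t over the columns of X given +1/-1 labels.
# Returns a data.frame with t and p per feature (degenerate -> p = 1).
ttestMap <- function(X, y) {
  a <- X[y == 1, , drop = FALSE]     # AD
  b <- X[y == -1, , drop = FALSE]    # Normal
  na <- nrow(a); nb <- nrow(b)
  df <- na + nb - 2L
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- sp2 <= 0
  d <- ma - mb
  t[degen] <- ifelse(d[degen] == 0, NA_real_, sign(d[degen]) * Inf)
  p[degen] <- ifelse(d[degen] == 0, 1, 0)
  data.frame(t = t, p = p, degenerate = degen)
}

#' t-test baseline feature selector
#'
#' Selects voxels by the voxelwise Student's t contrast, either every
#' feature with p below `alphaOrFraction` (no multiple-comparison
#' correction — the deliberate baseline convention) or the top
#' `alphaOrFraction` fraction with smallest p.
#'
#' @param X a [FeatureMatrix-class] or samples x M matrix.
#' @param y labels in \{-1, +1\} (taken from `X` when omitted).
#' @param mode `"p_threshold"` or `"top_fraction"`.
#' @param alphaOrFraction the significance level (default 0.05) or the
#'   fraction of features to keep.
#' @return a [SelectionMask-class].
#' @export
ttestSelect <- function(X, y = NULL, mode = c("p_threshold", "top_fraction"),
                        alphaOrFraction = 0.05) {
  mode <- match.arg(mode)
  vmap <- NULL; dims <- NULL
  if (is(X, "FeatureMatrix")) {
    if (is.null(y)) y <- X@labels
    vmap <- X@voxelMap; dims <- X@dims
    X <- X@values
  }
  X <- as.matrix(X)
  M <- ncol(X)
  tm <- ttestMap(X, y)
  idx <- if (mode == "p_threshold") {
    which(tm$p < alphaOrFraction)
  } else {
    k <- as.integer(ceiling(alphaOrFraction * M))
    order(tm$p, seq_len(M))[seq_len(k)]   # deterministic tie policy
  }
  if (!length(idx)) warning("t-test selection is empty")
  if (is.null(vmap)) {
    vmap <- cbind(seq_len(M), 1L, 1L)
    storage.mode(vmap) <- "integer"
    dims <- c(M, 1L, 1L)
  }
  new("SelectionMask", featureIndices = as.integer(sort(idx)),
      voxelMap = vmap, dims = as.integer(dims))
}

#' Compare the t-test and SVM-RFE selection pipelines
#'
#' Runs both selectors over the sliding-window subsets and pooled over the
#' whole cohort, then scores each selected feature set by leave-10-out
#' accuracy. Pooled rows evaluate features selected using the complete
#' sample, so their cross-validation is not strict — the selection saw the
#' test subjects; this caveat is carried in the `note` column.
#'
#' @param cohort a [PhantomCohort-class].
#' @param scheme a [SubsetScheme-class] consistent with the cohort.
#' @param C,tau,fraction SVM penalty, RFE step, top fraction selected.
#' @param alpha t-test significance level.
#' @param consensusThresholds fractions of the sets a voxel must be
#'   selected by for the pooled consensus rows.
#' @param foldSeed fold assignment seed.
#' @return data.frame with one row per selector/scope/threshold:
#'   `selector`, `scope`, `threshold`, `n_features`, `accuracy_pct`,
#'   `accuracy_sd`, `note`.
#' @export
compareSelectors <- function(cohort, scheme, C = 1, tau = 0.04,
                             fraction = 0.2, alpha = 0.05,
                             consensusThresholds = c(0.44, 0.56, 0.75, 1.0),
                             foldSeed = 1L) {
  stopifnot(is(cohort, "PhantomCohort"), is(scheme, "SubsetScheme"))
  universe <- featureUniverse(cohort)
  fmAll <- buildFeatureMatrix(cohort, universe)
  M <- nFeatures(fmAll)
  rows <- list()
  note_pooled <- "selection used the complete sample; not a strict CV"

  evalMask <- function(fm, mask, selector, seed) {
    idx <- featureIndices(mask)
    if (!length(idx)) return(c(NA_real_, NA_real_, 0))
    rep_ <- leave10outAccuracy(subsetFeatures(fm, idx), C = C,
                               foldSeed = seed, selector = selector)
    c(rep_@accuracyPct, stats::sd(rep_@foldAccuracies), length(idx))
  }

  # per-subset: select within each subset, evaluate within it
  accT <- accR <- matrix(NA_real_, scheme@nSets, 2L)
  nT <- nR <- integer(scheme@nSets)
  for (k in seq_len(scheme@nSets)) {
    sub <- scheme@subsets[[k]]
    fm <- buildFeatureMatrix(cohort, universe, c(sub$normal, sub$ad))
    seedk <- childSeed(foldSeed, k)
    mT <- ttestSelect(fm, mode = "p_threshold", alphaOrFraction = alpha)
    r <- evalMask(fm, mT, "ttest_p", seedk)
    accT[k, ] <- r[1:2]; nT[k] <- r[3]
    res <- svmRFE(fm, C = C, tau = tau)
    mR <- selectTopFraction(res, fraction, fm@voxelMap, fm@dims)
    r <- evalMask(fm, mR, "svm_rfe", seedk)
    accR[k, ] <- r[1:2]; nR[k] <- r[3]
  }
  rows[[1]] <- data.frame(
    selector = c("ttest_p", "svm_rfe"), scope = "per_subset",
    threshold = c(alpha, fraction),
    n_features = c(mean(nT), mean(nR)),
    accuracy_pct = c(mean(accT[, 1], na.rm = TRUE), mean(accR[, 1], na.rm = TRUE)),
    accuracy_sd = c(stats::sd(accT[, 1]), stats::sd(accR[, 1])),
    note = "mean over subsets")

  # pooled t-test on the full cohort
  mT <- ttestSelect(fmAll, mode = "p_threshold", alphaOrFraction = alpha)
  r <- evalMask(fmAll, mT, "ttest_p", foldSeed)
  rows[[2]] <- data.frame(selector = "ttest_p", scope = "pooled",
                          threshold = alpha, n_features = r[3],
                          accuracy_pct = r[1], accuracy_sd = r[2],
                          note = note_pooled)

  # pooled consensus at the operating thresholds
  cm <- runConsensus(cohort, scheme, C = C, tau = tau, fraction = fraction,
                     universe = universe)
  for (th in consensusThresholds) {
    mask <- thresholdConsensus(cm, ceiling(th * cm@nSets))
    r <- evalMask(fmAll, mask, "svm_rfe", foldSeed)
    rows[[length(rows) + 1L]] <-
      data.frame(selector = "svm_rfe", scope = "pooled_consensus",
                 threshold = th, n_features = r[3],
                 accuracy_pct = r[1], accuracy_sd = r[2],
                 note = note_pooled)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
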