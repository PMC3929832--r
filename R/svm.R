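#' @include AllClasses.R features.R
NULL

#' Train a linear soft-margin SVM
#'
#' Fits the maximal-margin hyperplane g(x) = w'x + b separating the two
#' classes, with misclassification penalty `C`. The explicit weight vector
#' is recovered from the dual solution as w = sum_i y_i lambda_i x_i over
#' the support vectors; orientation is normalized so that positive
#' decision values correspond to the +1 (AD) class. No feature
#' standardization is applied: inputs are tissue probabilities already on
#' a common \[0, 1\] scale.
#'
#' @param X numeric matrix (samples x features) or a
#'   [FeatureMatrix-class] (its labels are used when `y` is missing).
#' @param y numeric labels in \{-1, +1\}.
#' @param C positive soft-margin penalty (default 1).
#' @param tol solver termination tolerance.
#' @return a [LinearSVMModel-class].
#' @examples
#' m <- trainLinearSVM(rbind(c(0, 0), c(2, 0)), c(-1, 1), C = 100)
#' weights(m); bias(m)
#' @export
trainLinearSVM <- function(X, y = NULL, C = 1, tol = 1e-6) {
  if (is(X, "FeatureMatrix")) {
    if (is.null(y)) y <- X@labels
    X <- X@values
  }
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in training data")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  if (C <= 0) stop("C must be positive")
  # The dual problem depends on the samples only through the Gram matrix
  # K = X X'. For M >> n (voxel features), factor K = Z Z' with Z n x n and
  # solve in that span: the duals, objective and threshold are identical,
  # and w is recovered exactly from the duals afterwards.
  n <- nrow(X)
  Xfit <- X
  if (ncol(X) > n) {
    K <- tcrossprod(X)
    eig <- eigen(K, symmetric = TRUE)
    Xfit <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), n)
  }
  fit <- e1071::svm(Xfit, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = C, scale = FALSE, tolerance = tol)
  coefs <- drop(fit$coefs)                      # y_i * lambda_i, libsvm order
  b <- -fit$rho
  # libsvm assigns the positive decision side to the first class it
  # encounters; flip so the +1 class is the positive side
  pos <- strsplit(colnames(fit$decision.values), "/")[[1L]][1L]
  if (pos == "-1") {
    b <- -b; coefs <- -coefs
  }
  lam <- numeric(n)
  lam[fit$index] <- coefs * y[fit$index]        # lambda_i = (y_i lam_i) * y_i
  lam <- pmin(pmax(lam, 0), C)
  w <- weightFromDuals(lam, y, X)
  new(Class = "LinearSVMModel", w = as.numeric(w), b = b, C = C,
      duals = lam, supportIndices = as.integer(sort(fit$index)))
}

#' Evaluate the SVM decision function
#'
#' Returns g(x) = w'x + b for one or more feature vectors; the predicted
#' class is the sign (+1 = AD side).
#'
#' @param model a [LinearSVMModel-class].
#' @param x numeric vector of length M, or a samples x M matrix.
#' @return numeric decision value(s).
#' @export
decisionFunction <- function(model, x) {
  stopifnot(is(model, "LinearSVMModel"))
  if (is.null(dim(x))) {
    if (length(x) != length(model@w))
      stop("feature vector length ", length(x),
           " does not match model dimension ", length(model@w))
    return(sum(model@w * x) + model@b)
  }
  if (ncol(x) != length(model@w))
    stop("feature matrix has ", ncol(x), " columns; model expects ",
         length(model@w))
  drop(x %*% model@w + model@b)
}

#' Recover the weight vector from dual coefficients
#'
#' w = sum_i y_i lambda_i x_i, the weighted sum of the support vectors.
#' Used to validate solver output and as the RFE ranking score.
#'
#' @param duals numeric Lagrange multipliers lambda_i.
#' @param labels numeric class labels y_i in \{-1, +1\}.
#' @param samples numeric matrix of the corresponding sample vectors
#'   (rows aligned with `duals` and `labels`).
#' @return numeric weight vector of length `ncol(samples)`.
#' @examples
#' weightFromDuals(c(0.5, 0.5), c(1, -1), rbind(c(2, 0), c(0, 0)))
#' @export
weightFromDuals <- function(duals, labels, samples) {
  samples <- as.matrix(samples)
  if (length(duals) != length(labels) || length(duals) != nrow(samples))
    stop("duals, labels and samples must be aligned")
  drop(t(samples) %*% (duals * labels))
}

# Dual objective sum(lambda) - 1/2 lambda' Q lambda with Q = (y y') * (X X');
# used for cross-checks against an independent QP solve.
dualObjective <- function(duals, labels, samples) {
  samples <- as.matrix(samples)
  u <- duals * labels
  v <- drop(samples %*% (t(samples) %*% u))
  sum(duals) - 0.5 * sum(u * v)
}
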