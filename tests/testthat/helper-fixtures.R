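# Shared fixtures: tiny phantoms and random separable instances.

tinyParams <- function(..., seed = 1L) {
  phantomParams(dims = c(12L, 12L, 12L), nPerClass = 4L,
                roiSpec = matrix(c(6, 6, 6, 2), 1), noiseSd = 0.05,
                smoothFwhm = 0, seed = seed, ...)
}

deskParams <- function(..., seed = 1L) {
  phantomParams(seed = seed, ...)   # package defaults: 32^3, 30/class
}

# Random two-class instance with one informative direction.
randomInstance <- function(n, M, sep = 1, seed = 1L) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(rnorm(n * M), n)
  X[, 1] <- X[, 1] + sep * y
  list(X = X, y = y)
}

# Independent dual QP solve of the soft-margin SVM via a generic
# interior-point solver; returns the optimal duals.
ipopDuals <- function(X, y, C) {
  n <- nrow(X)
  H <- (y %*% t(y)) * tcrossprod(X)
  sol <- kernlab::ipop(c = rep(-1, n), H = H + diag(1e-10, n),
                       A = t(y), b = 0, l = rep(0, n), u = rep(C, n),
                       r = 0, sigf = 9, maxiter = 300)
  kernlab::primal(sol)
}

# Dual objective sum(lambda) - 1/2 lambda' (yy' * XX') lambda, written
# independently of the package internals.
dualObj <- function(lam, X, y) {
  u <- lam * y
  sum(lam) - 0.5 * drop(t(u) %*% tcrossprod(X) %*% u)
}

# Step-by-step oracle: textbook RFE with tau = 1, retraining after each
# removal and discarding the argmin |w_n| (ties: lowest index). Returns
# features in elimination order, first out first.
rfeOracleOrder <- function(X, y, C = 1) {
  surviving <- seq_len(ncol(X))
  out <- integer(0)
  while (length(surviving) > 1) {
    m <- trainLinearSVM(X[, surviving, drop = FALSE], y, C = C)
    aw <- abs(weights(m))
    drop_ <- surviving[order(aw, surviving)[1]]
    out <- c(out, drop_)
    surviving <- setdiff(surviving, drop_)
  }
  c(out, surviving)
}
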