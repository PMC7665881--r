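#' Canonical correlation analysis of 2-D phase statistics vs 3-D morphology
#'
#' Classical CCA between two feature sets measured on the same cells:
#' find coefficient vectors a, b maximizing cor(U, W) for the canonical
#' variates U = Xa, W = Yb, successive pairs uncorrelated with all earlier
#' ones, k = min(p, q) pairs in total. Solved by singular value
#' decomposition of the whitened cross-covariance
#' `Sxx^(-1/2) Sxy Syy^(-1/2)` (symmetric inverse square roots by
#' eigendecomposition, with a small ridge on near-singular within-set
#' covariances). Within-set loadings are the correlations between each
#' original variable and its own set's variates; shared variance is the
#' squared canonical correlation.
#'
#' @name cca
NULL

#' Standardize columns to zero mean and unit variance
#'
#' Population scaling (divisor n), matching the covariance convention used
#' by the CCA solver.
#'
#' @param m numeric matrix, n >= 2 rows.
#' @return matrix with each column at mean 0, population variance 1.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 rows")
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  sd_pop <- sqrt(colMeans(ctr^2))
  bad <- which(sd_pop == 0)
  if (length(bad)) {
    nm <- colnames(m)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop(sprintf("constant column(s): %s", paste(nm, collapse = ", ")))
  }
  sweep(ctr, 2L, sd_pop, `/`)
}

# symmetric inverse square root with optional ridge for near-singular input
sym_inv_sqrt <- function(S, ridge = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-10) {
    warning("near-singular within-set covariance; adding ridge 1e-8")
    e <- eigen(S + diag(ridge, nrow(S)), symmetric = TRUE)
  }
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

#' Fit canonical correlation analysis
#'
#' @param X n x p predictor matrix (standardized internally).
#' @param Y n x q response matrix; requires `n > p + q`.
#' @return a `CCAResult` list: `correlations` (non-increasing, in `[0, 1]`),
#'   `coeff_x` (p x k), `coeff_y` (q x k), `variates_x`, `variates_y`
#'   (n x k, unit population variance), `loadings_x`, `loadings_y`,
#'   `shared_variance` (squared correlations). The sign of each pair is
#'   fixed so the largest-|loading| X variable loads positively.
#' @export
cca_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  p <- ncol(X); q <- ncol(Y)
  if (n <= p + q) stop(sprintf("need n > p + q (n = %d, p + q = %d)", n, p + q))
  Xs <- standardize(X); Ys <- standardize(Y)
  Sxx <- crossprod(Xs) / n
  Syy <- crossprod(Ys) / n
  Sxy <- crossprod(Xs, Ys) / n
  Wx <- sym_inv_sqrt(Sxx)
  Wy <- sym_inv_sqrt(Syy)
  K <- Wx %*% Sxy %*% Wy
  sv <- svd(K)
  k <- min(p, q)
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  A <- Wx %*% sv$u[, seq_len(k), drop = FALSE]
  B <- Wy %*% sv$v[, seq_len(k), drop = FALSE]
  U <- Xs %*% A
  W <- Ys %*% B
  Lx <- stats::cor(Xs, U)
  # sign convention: dominant X loading positive per pair
  for (i in seq_len(k)) {
    j <- which.max(abs(Lx[, i]))
    if (Lx[j, i] < 0) {
      A[, i] <- -A[, i]; B[, i] <- -B[, i]
      U[, i] <- -U[, i]; W[, i] <- -W[, i]
    }
  }
  Lx <- within_set_loadings(Xs, U)
  Ly <- within_set_loadings(Ys, W)
  dimnames(A) <- list(colnames(X), NULL)
  dimnames(B) <- list(colnames(Y), NULL)
  dimnames(Lx) <- list(colnames(X), NULL)
  dimnames(Ly) <- list(colnames(Y), NULL)
  structure(list(correlations = rho, coeff_x = A, coeff_y = B,
                 variates_x = U, variates_y = W,
                 loadings_x = Lx, loadings_y = Ly,
                 shared_variance = shared_variance(rho)),
            class = "CCAResult")
}

#' Within-set canonical loadings
#'
#' Pearson correlation between each original variable and each canonical
#' variate of the same set.
#'
#' @param original n x m matrix of (standardized) original variables.
#' @param variates n x k matrix of canonical variates.
#' @return m x k loading matrix, entries in `[-1, 1]`.
#' @export
within_set_loadings <- function(original, variates) {
  original <- as.matrix(original); variates <- as.matrix(variates)
  stopifnot(nrow(original) == nrow(variates))
  if (any(apply(variates, 2L, stats::sd) == 0))
    stop("zero-variance canonical variate")
  stats::cor(original, variates)
}

#' Shared variance of canonical pairs
#'
#' @param correlations canonical correlations in `[0, 1]`.
#' @return element-wise square.
#' @export
shared_variance <- function(correlations) {
  if (any(correlations < 0 | correlations > 1))
    stop("canonical correlations must lie in [0, 1]")
  correlations^2
}

#' @export
print.CCAResult <- function(x, ...) {
  cat("Canonical correlations:", paste(sprintf("%.3f", x$correlations),
                                       collapse = " "), "\n")
  cat("Shared variances:      ", paste(sprintf("%.3f", x$shared_variance),
                                       collapse = " "), "\n")
  invisible(x)
}
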