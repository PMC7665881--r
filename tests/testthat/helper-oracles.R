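# independent brute-force oracles, deliberately written along different code
# paths than the implementations they check

# Shapley by direct double enumeration: for each instance and feature, loop
# over subsets of the remaining features (combn), computing the value
# function from scratch with its own hybrid-row construction
brute_force_shapley <- function(model_fn, instance, background) {
  M <- length(instance)
  feats <- seq_len(M)
  v_of <- function(S) {
    H <- background
    if (length(S)) H[, S] <- matrix(instance[S], nrow(background),
                                    length(S), byrow = TRUE)
    mean(model_fn(H))
  }
  phi <- numeric(M)
  for (i in feats) {
    rest <- setdiff(feats, i)
    for (k in 0:length(rest)) {
      subs <- if (k == 0) list(integer(0)) else
        utils::combn(rest, k, simplify = FALSE)
      w <- factorial(k) * factorial(M - k - 1) / factorial(M)
      for (S in subs) phi[i] <- phi[i] + w * (v_of(c(S, i)) - v_of(S))
    }
  }
  phi
}

# canonical correlations by the direct eigenvalue formulation
# eig(Sxx^-1 Sxy Syy^-1 Syx), population covariances
brute_force_canonical_correlations <- function(X, Y) {
  Xs <- scale(X, scale = FALSE); Ys <- scale(Y, scale = FALSE)
  n <- nrow(X)
  Sxx <- crossprod(Xs) / n; Syy <- crossprod(Ys) / n
  Sxy <- crossprod(Xs, Ys) / n
  Mmat <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  ev <- sort(Re(eigen(Mmat, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(pmin(ev[seq_len(min(ncol(X), ncol(Y)))], 1), 0))
}
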