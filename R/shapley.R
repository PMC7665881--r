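#' Exact Shapley feature attribution
#'
#' Exact Shapley values by full coalition enumeration under the
#' interventional (marginal) value function: for feature set F of size M,
#' instance x and value function
#' `v(S) = E_b[ f(x_S, b_{F\\S}) ]` over an explicit background sample b,
#' `phi_i = sum_{S subset F\\{i}} |S|! (M-|S|-1)! / M! * (v(S u {i}) - v(S))`.
#' Enumeration over all 2^M coalitions is exact and feasible for M <= 16
#' (32768 coalitions at M = 15). Attributions are in the units of the model
#' output passed in (log-odds for the classifier margin).
#'
#' @name shapley
NULL

# number of set bits for each value in 0:(2^M - 1)
popcount_table <- function(M) {
  s <- 0:(2L^M - 1L)
  out <- integer(length(s))
  for (b in seq_len(M)) out <- out + as.integer(bitwAnd(s, 2L^(b - 1L)) > 0L)
  out
}

#' Margin (log-odds) prediction function of a classifier
#'
#' @param model an `rbc_classifier`.
#' @return function mapping a feature matrix to log-odds scores, suitable as
#'   `model_fn` for [shapley_exact()].
#' @export
classifier_margin_fn <- function(model) {
  stopifnot(inherits(model, "rbc_classifier"))
  features <- model$features
  function(X) {
    if (is.data.frame(X)) X <- as.matrix(X[, features, drop = FALSE])
    stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1L),
                   outputmargin = TRUE)
  }
}

#' Exact Shapley values by coalition enumeration
#'
#' @param model_fn function mapping a numeric feature matrix (rows =
#'   observations) to a numeric score vector.
#' @param instances matrix or data frame of instances to explain (columns =
#'   features, at most `max_features`).
#' @param background matrix or data frame of background rows defining the
#'   marginal expectation (e.g., a seeded sample of 100 training rows).
#' @param max_features refuse larger problems (cost 2^M model calls).
#' @param chunk coalitions evaluated per model call (batching only).
#' @return a `ShapleyResult` list: `attributions` (instances x features),
#'   `base_value` (expected model output over the background), `importance`
#'   (mean |attribution| per feature), `ranking` (features sorted by
#'   importance, ties broken by name order).
#' @export
shapley_exact <- function(model_fn, instances, background, max_features = 16L,
                          chunk = 64L) {
  if (is.data.frame(instances)) instances <- as.matrix(instances)
  if (is.data.frame(background)) background <- as.matrix(background)
  stopifnot(is.matrix(instances), is.matrix(background),
            ncol(instances) == ncol(background), nrow(background) >= 1L)
  M <- ncol(instances)
  if (M > max_features)
    stop(sprintf("%d features would need 2^%d = %.3g coalition evaluations; limit is %d features",
                 M, M, 2^M, max_features))
  n <- nrow(instances); B <- nrow(background)
  feat_names <- colnames(instances)
  if (is.null(feat_names)) feat_names <- paste0("x", seq_len(M))

  ncoal <- 2L^M
  # hybrid design: background block repeated per instance
  bg_big <- background[rep(seq_len(B), times = n), , drop = FALSE]
  inst_big <- instances[rep(seq_len(n), each = B), , drop = FALSE]
  rows_per_coal <- n * B

  V <- matrix(NA_real_, ncoal, n)   # V[s+1, i] = v(S) for instance i
  coals <- 0:(ncoal - 1L)
  bits <- 2L^(seq_len(M) - 1L)
  for (start in seq(1L, ncoal, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ncoal)
    H <- bg_big[rep(seq_len(rows_per_coal), times = length(idx)), , drop = FALSE]
    for (j in seq_along(idx)) {
      s <- coals[idx[j]]
      if (s == 0L) next
      in_s <- which(bitwAnd(s, bits) > 0L)
      rsel <- (j - 1L) * rows_per_coal + seq_len(rows_per_coal)
      H[rsel, in_s] <- inst_big[, in_s, drop = FALSE]
    }
    sc <- model_fn(H)
    sc <- matrix(sc, nrow = B)      # B x (n * length(idx))
    vmeans <- colMeans(sc)
    V[idx, ] <- matrix(vmeans, nrow = length(idx), ncol = n, byrow = TRUE)
  }

  sizes <- popcount_table(M)
  w <- exp(lfactorial(0:(M - 1L)) + lfactorial(M - (0:(M - 1L)) - 1L) - lfactorial(M))
  attr_mat <- matrix(0, n, M, dimnames = list(NULL, feat_names))
  for (i in seq_len(M)) {
    bit <- bits[i]
    without <- which(bitwAnd(coals, bit) == 0L)       # 1-based indices into V
    ww <- w[sizes[without] + 1L]
    diff_v <- V[without + bit, , drop = FALSE] - V[without, , drop = FALSE]
    attr_mat[, i] <- colSums(diff_v * ww)
  }

  importance <- colMeans(abs(attr_mat))
  ord <- order(-importance, feat_names)
  structure(list(attributions = attr_mat, base_value = V[1L, 1L],
                 importance = importance, ranking = feat_names[ord]),
            class = "ShapleyResult")
}

#' Global feature importance from Shapley attributions
#'
#' Features ranked by the mean absolute attribution over all explained
#' instances, descending; ties broken by feature-name order.
#'
#' @param s a `ShapleyResult`.
#' @return data frame with `feature` and `importance`, sorted.
#' @export
global_importance <- function(s) {
  stopifnot(inherits(s, "ShapleyResult"), nrow(s$attributions) >= 1L)
  imp <- colMeans(abs(s$attributions))
  nm <- names(imp)
  ord <- order(-imp, nm)
  data.frame(feature = nm[ord], importance = unname(imp[ord]))
}
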