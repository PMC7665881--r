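#' Gradient-boosted classification of thalassemic vs healthy cells
#'
#' A gradient-boosted decision-tree classifier (xgboost backend) on the
#' 15-feature table, with grouped data splitting (all augmented copies of a
#' cell stay in one partition, since ~10 interferograms are acquired per
#' physical cell and image-level splits would leak near-duplicates),
#' rotation-based class balancing, and the standard confusion-matrix /
#' rank-statistic evaluation metrics.
#'
#' @name classify
NULL

#' Group-wise dataset split
#'
#' Whole groups (e.g., all augmented copies of one cell) are randomly
#' assigned to partitions so that the partition sizes, counted in groups,
#' match the requested fractions as closely as integer counts allow.
#'
#' @param table data frame of per-cell rows.
#' @param ratios partition fractions summing to 1 (e.g. `c(4, 1) / 5`).
#' @param group_col column identifying the group of each row.
#' @param seed integer; fixed seed gives an identical split.
#' @return list of data frames, one per ratio, named `part1..partK` (or
#'   `train`/`test` for two partitions, `train`/`val`/`test` for three).
#' @export
split_dataset <- function(table, ratios = c(0.8, 0.2), group_col = "cell_id",
                          seed = 1L) {
  stopifnot(is.data.frame(table), group_col %in% names(table))
  ratios <- ratios / sum(ratios)
  groups <- unique(table[[group_col]])
  ng <- length(groups)
  sizes <- floor(ratios * ng)
  rem <- ng - sum(sizes)
  if (rem > 0) {
    top <- order(ratios * ng - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[top] <- sizes[top] + 1L
  }
  if (any(sizes < 1L))
    stop("a partition would receive no group; use more groups or fewer partitions")
  perm <- with_seed(seed, sample(groups))
  assign <- rep(seq_along(sizes), sizes)
  parts <- lapply(seq_along(sizes), function(i) {
    table[table[[group_col]] %in% perm[assign == i], , drop = FALSE]
  })
  names(parts) <- if (length(parts) == 2L) c("train", "test") else
    if (length(parts) == 3L) c("train", "val", "test") else
      paste0("part", seq_along(parts))
  parts
}

#' Balance classes by rotation augmentation
#'
#' Appends random-angle rotated copies of minority-class records until the
#' class counts are equal. Records are lists with `phase` ([phase_map()]),
#' `mask`, `class` and `cell_id`; augmented copies inherit the source
#' `cell_id` so grouped splitting keeps them together.
#'
#' @param records list of records as above.
#' @param rng_seed integer seed for the rotation angles and source draws.
#' @return augmented list of records (unchanged if already balanced).
#' @export
balance_by_rotation <- function(records, rng_seed = 1L) {
  classes <- vapply(records, `[[`, character(1L), "class")
  tab <- table(classes)
  if (length(tab) < 2L || diff(range(tab)) == 0L) return(records)
  minority <- names(tab)[which.min(tab)]
  deficit <- max(tab) - min(tab)
  src <- which(classes == minority)
  with_seed(rng_seed, {
    picks <- sample(src, deficit, replace = TRUE)
    angles <- stats::runif(deficit, 0, 360)
    for (i in seq_len(deficit)) {
      rec <- records[[picks[i]]]
      rot <- augment_rotate(rec$phase$phase, rec$mask, angles[i])
      rec$phase <- phase_map(rot$image, rec$phase$pixel_size,
                             provenance = rec$phase$provenance)
      rec$mask <- rot$mask
      rec$augmented <- TRUE
      records[[length(records) + 1L]] <- rec
    }
  })
  records
}

#' Train the gradient-boosted tree classifier
#'
#' @param train_table data frame with a `class` column and the 15 feature
#'   columns of [feature_columns_2d()].
#' @param positive_class class coded as 1 (default `"thal"`).
#' @param features feature columns to use.
#' @param max_depth,nrounds,eta hyperparameters (defaults: depth 3,
#'   200 rounds, learning rate 0.1, logistic loss).
#' @param seed integer seed; training is deterministic given the seed
#'   (single-threaded).
#' @return an object of class `rbc_classifier` wrapping the booster.
#' @export
train_classifier <- function(train_table, positive_class = "thal",
                             features = feature_columns_2d(),
                             max_depth = 3L, nrounds = 200L, eta = 0.1,
                             seed = 1L) {
  stopifnot(is.data.frame(train_table), "class" %in% names(train_table),
            all(features %in% names(train_table)))
  y <- as.integer(train_table$class == positive_class)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  X <- as.matrix(train_table[, features, drop = FALSE])
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(max_depth = max_depth, eta = eta,
                  objective = "binary:logistic", nthread = 1L, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0))
  structure(list(booster = booster, features = features,
                 positive_class = positive_class,
                 hyperparams = list(max_depth = max_depth, nrounds = nrounds,
                                    eta = eta, seed = seed)),
            class = "rbc_classifier")
}

#' Predict positive-class probability
#' @param object an `rbc_classifier`.
#' @param newdata data frame or matrix of features.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.rbc_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata))
    newdata <- as.matrix(newdata[, object$features, drop = FALSE])
  stats::predict(object$booster, xgboost::xgb.DMatrix(newdata, nthread = 1L))
}

#' Save / load a trained classifier
#'
#' The booster is persisted in xgboost's native format plus a JSON sidecar
#' of features, positive class, hyperparameters and seed.
#'
#' @param model an `rbc_classifier`.
#' @param dir output directory.
#' @return `dir` invisibly (save); an `rbc_classifier` (load).
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "rbc_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "model.ubj"))
  jsonlite::write_json(list(features = model$features,
                            positive_class = model$positive_class,
                            hyperparams = model$hyperparams),
                       file.path(dir, "model.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_classifier
#' @param dir directory written by `save_classifier`.
#' @export
load_classifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  structure(list(booster = xgboost::xgb.load(file.path(dir, "model.ubj")),
                 features = meta$features, positive_class = meta$positive_class,
                 hyperparams = as.list(meta$hyperparams)),
            class = "rbc_classifier")
}

# Mann-Whitney rank-statistic AUC with midranks for ties
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics on a test table
#'
#' Confusion-matrix metrics at the 0.5 probability threshold; AUC by the
#' Mann-Whitney rank statistic over predicted scores (reported `NA` when the
#' test set has one class). Row order of the test table does not matter.
#'
#' @param model an `rbc_classifier`, or `NULL` when `scores` are supplied.
#' @param test_table data frame with `class` and feature columns.
#' @param positive_class positive (sensitivity) class.
#' @param scores optional pre-computed scores overriding model prediction.
#' @return an `EvalMetrics` list: `sensitivity`, `specificity`, `accuracy`,
#'   `f1`, `auc`, `confusion` (tp, fn, tn, fp).
#' @export
evaluate <- function(model, test_table, positive_class = NULL, scores = NULL) {
  stopifnot(is.data.frame(test_table), nrow(test_table) > 0L,
            "class" %in% names(test_table))
  if (is.null(positive_class))
    positive_class <- if (!is.null(model)) model$positive_class else "thal"
  if (is.null(scores)) scores <- predict(model, test_table)
  y <- as.integer(test_table$class == positive_class)
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred == 1L & y == 1L); fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L); fp <- sum(pred == 1L & y == 0L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 f1 = f1, auc = auc_rank(scores, y),
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)),
            class = "EvalMetrics")
}

#' Metrics from confusion counts
#'
#' The same identities as [evaluate()] applied to given counts; used to
#' check published operating points (e.g., balanced classes with
#' sensitivity 0.971 and specificity 0.985 imply accuracy 0.978).
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return an `EvalMetrics` list (without AUC).
#' @export
metrics_from_confusion <- function(tp, fn, tn, fp) {
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  prec <- tp / (tp + fp)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 f1 = 2 * prec * sens / (prec + sens), auc = NA_real_,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)),
            class = "EvalMetrics")
}

#' @export
print.EvalMetrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.3f | specificity %.3f | accuracy %.3f | F1 %.3f | AUC %s\n",
    x$sensitivity, x$specificity, x$accuracy, x$f1,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}
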