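make_grouped_table <- function(n_cells = 100L, copies = 10L, seed = 1L) {
  set.seed(seed)
  cell_id <- rep(seq_len(n_cells), each = copies)
  X <- matrix(rnorm(n_cells * copies * 15L), ncol = 15L,
              dimnames = list(NULL, feature_columns_2d()))
  cbind(data.frame(cell_id = cell_id,
                   class = rep(c("healthy", "thal"),
                               length.out = n_cells)[cell_id]),
        as.data.frame(X))
}

test_that("grouped splitting keeps augmented copies together", {
  tab <- make_grouped_table()
  parts <- split_dataset(tab, ratios = c(4, 1) / 5, seed = 11L)
  expect_identical(length(unique(parts$train$cell_id)), 80L)
  expect_identical(length(unique(parts$test$cell_id)), 20L)
  expect_length(intersect(parts$train$cell_id, parts$test$cell_id), 0L)
  expect_identical(nrow(parts$train) + nrow(parts$test), nrow(tab))

  again <- split_dataset(tab, ratios = c(4, 1) / 5, seed = 11L)
  expect_identical(parts$train$cell_id, again$train$cell_id)

  three <- split_dataset(tab, ratios = c(0.6, 0.2, 0.2), seed = 2L)
  expect_named(three, c("train", "val", "test"))
  expect_identical(vapply(three, function(p) length(unique(p$cell_id)),
                          integer(1L)),
                   c(train = 60L, val = 20L, test = 20L))
})

test_that("rotation balancing equalizes class counts without leakage", {
  r <- classic_phantom()
  rec <- function(id, cls) list(phase = r$phase, mask = r$mask,
                                class = cls, cell_id = id)
  records <- c(lapply(1:6, rec, cls = "thal"),
               lapply(7:9, rec, cls = "healthy"))
  out <- balance_by_rotation(records, rng_seed = 4L)
  classes <- vapply(out, `[[`, character(1L), "class")
  expect_identical(unname(table(classes)["healthy"]),
                   unname(table(classes)["thal"]))
  aug <- out[(length(records) + 1L):length(out)]
  expect_true(all(vapply(aug, `[[`, numeric(1L), "cell_id") %in% 7:9))
  expect_true(all(vapply(aug, `[[`, logical(1L), "augmented")))

  balanced <- c(lapply(1:3, rec, cls = "thal"), lapply(4:6, rec, cls = "healthy"))
  expect_identical(balance_by_rotation(balanced, rng_seed = 1L), balanced)
})

test_that("training is deterministic and rejects degenerate input", {
  ft <- population_features()
  parts <- split_dataset(ft, seed = 5L)
  m1 <- train_classifier(parts$train, seed = 8L)
  m2 <- train_classifier(parts$train, seed = 8L)
  probe <- parts$test
  expect_identical(predict(m1, probe), predict(m2, probe))

  single <- parts$train[parts$train$class == "thal", ]
  expect_error(train_classifier(single), "both classes")
})

test_that("shuffled labels give chance-level accuracy", {
  tab <- make_grouped_table(n_cells = 200L, copies = 5L, seed = 3L)
  tab$class <- with_seed(6L, sample(tab$class))
  parts <- split_dataset(tab, seed = 7L)
  model <- train_classifier(parts$train, seed = 7L)
  acc <- evaluate(model, parts$test)$accuracy
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)
})

test_that("evaluation metrics match hand-counted confusion tables", {
  m <- metrics_from_confusion(tp = 3, fn = 1, tn = 4, fp = 2)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 2 / 3, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.70)
  expect_equal(m$f1, 2 * (3 / 5) * 0.75 / (3 / 5 + 0.75), tolerance = 1e-12)

  # perfect separation scores 1 everywhere
  tab <- data.frame(class = rep(c("thal", "healthy"), each = 10L))
  scores <- c(rep(0.9, 10L), rep(0.1, 10L))
  pm <- evaluate(NULL, tab, positive_class = "thal", scores = scores)
  expect_equal(unlist(pm[c("sensitivity", "specificity", "accuracy",
                           "f1", "auc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, f1 = 1,
                 auc = 1))
})

test_that("evaluation is row-order invariant and AUC matches pROC", {
  set.seed(12)
  tab <- data.frame(class = sample(rep(c("thal", "healthy"), each = 50L)))
  scores <- ifelse(tab$class == "thal", rnorm(100, 1), rnorm(100, 0))
  m1 <- evaluate(NULL, tab, positive_class = "thal", scores = scores)
  ord <- sample(nrow(tab))
  m2 <- evaluate(NULL, tab[ord, , drop = FALSE], positive_class = "thal",
                 scores = scores[ord])
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
  expect_identical(m1$confusion, m2$confusion)

  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(tab$class == "thal"), predictor = scores,
    quiet = TRUE, direction = "<")))
  expect_equal(m1$auc, ref, tolerance = 1e-12)
})

test_that("a saved classifier reloads with identical predictions", {
  ft <- population_features()
  parts <- split_dataset(ft, seed = 9L)
  model <- train_classifier(parts$train, seed = 9L)
  dir <- tempfile("model")
  save_classifier(model, dir)
  back <- load_classifier(dir)
  expect_equal(predict(back, parts$test), predict(model, parts$test),
               tolerance = 1e-12)
  expect_identical(back$features, model$features)
})

test_that("classifiers on watershed and truth masks learn the same rules", {
  specs <- sample_population(60L, rng_seed = 19L)
  ft_truth <- suppressMessages(population_feature_table(
    specs, segment = "truth", rng_seed = 19L))
  ft_ws <- suppressMessages(population_feature_table(
    specs, segment = "watershed", rng_seed = 19L))
  rank_of <- function(ft) {
    parts <- split_dataset(ft, seed = 20L)
    model <- train_classifier(parts$train, seed = 21L)
    bg <- parts$train[with_seed(22L, sample(nrow(parts$train), 15L)),
                      model$features]
    inst <- parts$test[with_seed(23L, sample(nrow(parts$test), 10L)),
                       model$features]
    global_importance(shapley_exact(classifier_margin_fn(model), inst, bg))
  }
  gi_t <- rank_of(ft_truth)
  gi_w <- rank_of(ft_ws)
  expect_setequal(head(gi_t$feature, 4L), head(gi_w$feature, 4L))
})
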