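test_that("standardization uses population scaling and guards constants", {
  out <- standardize(matrix(c(1, 2, 3), 3L, 1L))
  expect_equal(as.numeric(out), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(as.numeric(out), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  again <- standardize(out)
  expect_equal(again, out, tolerance = 1e-12)

  m <- matrix(rnorm(20), 10L, 2L, dimnames = list(NULL, c("x", "const")))
  m[, 2L] <- 5
  expect_error(standardize(m), "const")
})

test_that("identical sets give unit correlations; k = min(p, q)", {
  set.seed(41)
  X <- matrix(rnorm(200 * 4), 200L, 4L)
  fit <- cca_fit(X, X)
  expect_equal(fit$correlations, rep(1, 4L), tolerance = 1e-8)

  Y <- matrix(rnorm(200 * 6), 200L, 6L)
  fit46 <- cca_fit(X, Y)
  expect_length(fit46$correlations, 4L)
  expect_identical(ncol(fit46$coeff_x), 4L)
  expect_identical(ncol(fit46$coeff_y), 4L)
  expect_length(fit46$shared_variance, 4L)

  expect_error(cca_fit(X[1:8, ], Y[1:8, ]), "n > p \\+ q")
})

test_that("canonical variates satisfy the defining constraints", {
  set.seed(42)
  n <- 300L
  z <- rnorm(n)
  X <- cbind(z + rnorm(n), rnorm(n), rnorm(n), rnorm(n))
  Y <- cbind(0.7 * z + rnorm(n), rnorm(n), rnorm(n), rnorm(n), rnorm(n),
             rnorm(n))
  fit <- cca_fit(X, Y)
  U <- fit$variates_x; W <- fit$variates_y
  pop_var <- function(v) mean((v - mean(v))^2)
  expect_equal(apply(U, 2L, pop_var), rep(1, 4L), tolerance = 1e-8)
  expect_equal(apply(W, 2L, pop_var), rep(1, 4L), tolerance = 1e-8)
  cu <- cor(U); cw <- cor(W)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-8)
  expect_lt(max(abs(cw[upper.tri(cw)])), 1e-8)
  for (i in 1:4)
    expect_equal(cor(U[, i], W[, i]), fit$correlations[i], tolerance = 1e-8)
  expect_equal(fit$shared_variance, fit$correlations^2, tolerance = 1e-12)
  expect_true(all(diff(fit$correlations) <= 1e-12))
})

test_that("correlations match the brute-force eigenvalue formulation", {
  set.seed(43)
  for (rep in 1:50) {
    n <- 500L
    L <- matrix(rnorm(16), 4L, 4L)
    Z <- matrix(rnorm(n * 4L), n, 4L)
    X <- Z %*% L + matrix(rnorm(n * 4L), n, 4L)
    Y <- cbind(Z %*% matrix(rnorm(4 * 6), 4L, 6L) +
                 matrix(rnorm(n * 6L), n, 6L))
    fit <- cca_fit(X, Y)
    oracle <- brute_force_canonical_correlations(X, Y)
    expect_equal(fit$correlations, oracle, tolerance = 1e-8)
  }
})

test_that("correlations are invariant under invertible remixing of X", {
  set.seed(44)
  n <- 400L
  X <- matrix(rnorm(n * 4L), n, 4L)
  Y <- X[, 1:2] %*% matrix(rnorm(12), 2L, 6L) + matrix(rnorm(n * 6L), n, 6L)
  A <- matrix(rnorm(16), 4L, 4L) + diag(4) * 2
  fit1 <- cca_fit(X, Y)
  fit2 <- cca_fit(X %*% A, Y)
  expect_equal(fit1$correlations, fit2$correlations, tolerance = 1e-8)
})

test_that("a single shared latent factor is recovered at its construction strength", {
  set.seed(1)
  n <- 10000L
  z <- rnorm(n)
  X <- cbind(z, matrix(rnorm(n * 3L), n, 3L))
  Y <- cbind(0.8 * z + sqrt(1 - 0.8^2) * rnorm(n),
             matrix(rnorm(n * 5L), n, 5L))
  fit <- cca_fit(X, Y)
  expect_gte(fit$correlations[1L], 0.78)
  expect_lte(fit$correlations[1L], 0.82)
  expect_lt(fit$correlations[2L], 0.1)
})

test_that("within-set loadings equal an independent correlation loop", {
  set.seed(45)
  X <- matrix(rnorm(200 * 4L), 200L, 4L)
  Y <- matrix(rnorm(200 * 6L), 200L, 6L)
  fit <- cca_fit(X, Y)
  Xs <- standardize(X)
  manual <- matrix(0, 4L, 4L)
  for (j in 1:4) for (i in 1:4)
    manual[j, i] <- cor(Xs[, j], fit$variates_x[, i])
  expect_equal(unname(fit$loadings_x), manual, tolerance = 1e-12)
  expect_true(all(abs(fit$loadings_x) <= 1 + 1e-12))

  single <- within_set_loadings(X[, 1L, drop = FALSE],
                                X[, 1L, drop = FALSE] * 2)
  expect_equal(abs(as.numeric(single)), 1, tolerance = 1e-12)
})

test_that("shared variance squares the correlations and checks its domain", {
  expect_equal(shared_variance(0.87), 0.7569, tolerance = 1e-12)
  expect_identical(round(shared_variance(0.87), 2), 0.76)
  expect_identical(shared_variance(c(0, 1)), c(0, 1))
  expect_error(shared_variance(1.2), "\\[0, 1\\]")
})

test_that("the phantom population reproduces the canonical structure", {
  ft <- population_features()
  xcols <- c("ov_rad_um2", "phase_mean_rad", "phase_p5_rad", "phase_sd_rad")
  ycols <- c("volume_um3", "sv_ratio_per_um", "sphericity", "t_avg_um",
             "t_0_um", "delta_75_um")
  fit <- cca_fit(ft[, xcols], ft[, ycols])
  expect_length(fit$correlations, 4L)
  # first pair links optical volume with volume
  expect_identical(rownames(fit$loadings_x)[which.max(abs(fit$loadings_x[, 1L]))],
                   "ov_rad_um2")
  expect_identical(rownames(fit$loadings_y)[which.max(abs(fit$loadings_y[, 1L]))],
                   "volume_um3")
  # second pair: phase SD with S/V and delta75, against sphericity
  s <- unname(sign(fit$loadings_x["phase_sd_rad", 2L]))
  expect_identical(unname(sign(fit$loadings_y["sv_ratio_per_um", 2L])), s)
  expect_identical(unname(sign(fit$loadings_y["delta_75_um", 2L])), s)
  expect_identical(unname(sign(fit$loadings_y["sphericity", 2L])), -s)
})
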