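test_that("phase statistics match closed forms", {
  m <- matrix(0, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE          # 100 px
  m[mask] <- 1
  st <- phase_statistics(phase_map(m, 0.1, provenance = "synthetic"), mask)
  expect_equal(st$ov, 1.0, tolerance = 1e-12)
  expect_equal(st$phase_mean, 1)
  expect_equal(st$phase_p5, 1)
  expect_equal(st$phase_p95, 1)
  expect_equal(st$phase_sd, 0)
  expect_false(st$degenerate)

  m2 <- matrix(0, 10, 10); m2[] <- 1:100
  st2 <- phase_statistics(phase_map(m2, 1, provenance = "synthetic"),
                          matrix(TRUE, 10, 10))
  expect_equal(st2$phase_p5, 5.95, tolerance = 1e-12)
  expect_equal(st2$phase_p95, 95.05, tolerance = 1e-12)
  expect_equal(st2$phase_sd, sqrt(mean((1:100 - 50.5)^2)), tolerance = 1e-12)
})

test_that("optical volume of the discocyte phantom matches the forward model", {
  r <- classic_phantom()
  st <- phase_statistics(r$phase, r$mask)
  expected <- 2 * pi * 0.06 / 0.532 * r$truth$volume_um3
  expect_lt(abs(st$ov - expected) / expected, 0.01)
})

test_that("2-D morphology matches analytic shapes", {
  n <- 61L
  disc <- disc_mask(n, 20)
  mo <- morphology2d(disc, 0.1)
  expect_lt(abs(mo$area - pi * 4) / (pi * 4), 0.01)
  expect_lt(abs(mo$perimeter - 2 * pi * 2) / (2 * pi * 2), 0.02)
  expect_lt(mo$eccentricity, 0.1)

  n2 <- 121L
  xy <- expand.grid(seq_len(n2), seq_len(n2))
  ell <- matrix(((xy[, 1L] - 61) / 40)^2 + ((xy[, 2L] - 61) / 20)^2,
                n2, n2) <= 1
  mo2 <- morphology2d(ell, 0.1)
  expect_equal(mo2$eccentricity, sqrt(1 - 1 / 4), tolerance = 0.01)
  expect_gte(mo2$major_axis, mo2$minor_axis)

  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  mo3 <- morphology2d(single, 0.1)
  expect_equal(mo3$area, 0.01, tolerance = 1e-12)
  expect_identical(mo3$major_axis, mo3$minor_axis)
  expect_identical(mo3$eccentricity, 0)
  expect_true(mo3$degenerate)

  two <- matrix(FALSE, 9, 9); two[2, 2] <- TRUE; two[7, 7] <- TRUE
  expect_error(morphology2d(two, 0.1), "2 connected components")
})

test_that("GLCM features reproduce the hand-counted two-level example", {
  img <- matrix(c(0, 0, 1, 1), 2, 2)   # [[0,1],[0,1]] row-wise
  p <- phase_map(img, 1, provenance = "synthetic")
  g <- glcm_features(p, matrix(TRUE, 2, 2), levels = 2L, angles = 0)
  expect_equal(g$contrast, 1, tolerance = 1e-12)
  expect_equal(g$dissimilarity, 1, tolerance = 1e-12)
  expect_equal(g$homogeneity, 0.5, tolerance = 1e-12)
  expect_equal(g$asm, 0.5, tolerance = 1e-12)
  expect_equal(g$energy, sqrt(0.5), tolerance = 1e-12)
})

test_that("GLCM handles constant cells and satisfies energy^2 = asm", {
  p <- phase_map(matrix(2, 10, 10), 1, provenance = "synthetic")
  g <- glcm_features(p, matrix(TRUE, 10, 10))
  expect_true(g$constant)
  expect_equal(unlist(g[c("contrast", "dissimilarity")]),
               c(contrast = 0, dissimilarity = 0))
  expect_equal(unlist(g[c("homogeneity", "energy", "asm")]),
               c(homogeneity = 1, energy = 1, asm = 1))

  set.seed(11)
  rnd <- phase_map(matrix(runif(400), 20, 20), 1, provenance = "synthetic")
  mask <- disc_mask(20, 8)
  g2 <- glcm_features(rnd, mask)
  expect_lt(abs(g2$energy^2 - g2$asm), 1e-12)
  expect_true(g2$homogeneity > 0 && g2$homogeneity <= 1)
})

test_that("the extractor emits one 15-feature row per interior cell", {
  specs <- sample_population(2L, rng_seed = 21L)[1:3]
  scene <- compose_scene(specs, shape = c(360L, 360L), pixel_size = 0.08,
                         min_gap_px = 8, rng_seed = 3L)
  tab <- extract_features(scene$phase, scene$labels, class = "healthy")
  expect_identical(nrow(tab), 3L)
  expect_identical(setdiff(names(tab), c("cell_id", "class")),
                   feature_columns_2d())
  expect_length(feature_columns_2d(), 15L)
  expect_true(all(is.finite(as.matrix(tab[, feature_columns_2d()]))))

  empty <- extract_features(scene$phase,
                            label_map(matrix(0L, 360, 360), 0.08))
  expect_identical(nrow(empty), 0L)
  expect_identical(setdiff(names(empty), c("cell_id", "class")),
                   feature_columns_2d())
})

test_that("border-touching cells are excluded with a message", {
  lab <- matrix(0L, 60, 60)
  lab[1:10, 20:30] <- 1L           # touches row 1
  lab[30:40, 30:40] <- 2L
  p <- phase_map(matrix(runif(3600), 60, 60), 0.1, provenance = "synthetic")
  expect_message(tab <- extract_features(p, label_map(lab, 0.1)),
                 "border-touching")
  expect_identical(nrow(tab), 1L)
})

test_that("phase statistics are exactly invariant under 90-degree rotation", {
  r <- classic_phantom()
  lm <- label_map(r$mask * 1L, r$phase$pixel_size)
  f0 <- extract_features(r$phase, lm)
  rot <- augment_rotate(r$phase$phase, r$mask, 90)
  f1 <- extract_features(phase_map(rot$image, r$phase$pixel_size,
                                   provenance = "synthetic"),
                         label_map(rot$mask * 1L, r$phase$pixel_size))
  for (v in c("ov_rad_um2", "phase_mean_rad", "phase_p5_rad",
              "phase_p95_rad", "phase_sd_rad"))
    expect_equal(f1[[v]], f0[[v]], tolerance = 1e-9)
})

test_that("all 15 features are finite across the phantom population", {
  ft <- population_features()
  expect_identical(nrow(ft), 200L)
  expect_true(all(is.finite(as.matrix(ft[, feature_columns_2d()]))))
  # ov = mean * area identity
  expect_equal(ft$ov_rad_um2, ft$phase_mean_rad * ft$area_um2,
               tolerance = 1e-6)
})

test_that("population contrasts follow the thalassemic phenotype", {
  ft <- population_features()
  h <- ft[ft$class == "healthy", ]; t <- ft[ft$class == "thal", ]
  pooled_se <- function(v) sqrt(var(h[[v]]) / nrow(h) + var(t[[v]]) / nrow(t))
  expect_lt(mean(t$ov_rad_um2),
            mean(h$ov_rad_um2) - 3 * pooled_se("ov_rad_um2"))
  expect_gt(mean(t$phase_sd_rad),
            mean(h$phase_sd_rad) + 3 * pooled_se("phase_sd_rad"))
  expect_lt(mean(t$phase_mean_rad), mean(h$phase_mean_rad))
  expect_lt(mean(t$phase_p5_rad), mean(h$phase_p5_rad))
})
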