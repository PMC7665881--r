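test_that("discocyte thickness matches the Evans-Fung closed forms", {
  ps <- 0.08
  n <- 101L
  ctr <- c(50.5 * ps, 50.5 * ps)   # exactly the centre of pixel (51, 51)
  spec <- phantom_spec(center = ctr)
  t <- discocyte_thickness(spec, c(n, n), ps)
  expect_equal(t$thickness[51L, 51L], 0.81, tolerance = 1e-9)
  expect_lt(abs(sum(t$thickness) * ps^2 - 94.1) / 94.1, 0.02)
  expect_true(all(t$thickness >= 0))

  dome <- phantom_spec(shape_coeffs = c(1.5, 0, 0), center = ctr)
  td <- discocyte_thickness(dome, c(n, n), ps)
  expect_equal(td$thickness[51L, 51L], 1.5, tolerance = 1e-9)

  expect_error(phantom_spec(shape_coeffs = c(0.1, 0, -1)), "negative")
  expect_error(discocyte_thickness(spec, c(30L, 30L), 0.5), "resolve")
})

test_that("the phase forward model is the thin-object projection", {
  ps <- 0.1
  t <- thickness_map(ifelse(disc_mask(40, 10), 2, 0), ps)
  p <- phase_forward(t, 0.06, 0.532)
  expect_equal(max(p$phase), 2 * pi * 0.06 * 2 / 0.532, tolerance = 1e-12)
  expect_equal(max(p$phase), 1.41726, tolerance = 1e-4)
  p2 <- phase_forward(t, 0.12, 0.532)
  expect_equal(p2$phase, 2 * p$phase, tolerance = 1e-12)
  expect_true(all(p$phase[!t$mask] == 0))
})

test_that("synthetic holograms carry the carrier and are reproducible", {
  p <- phase_map(matrix(0, 96, 96), 0.1, provenance = "synthetic")
  carrier <- c(0.125, 0.25)    # exact FFT bins on a 96-px grid: 12 and 24
  h <- hologram_forward(p, carrier = carrier, noise_sd = 0)
  F <- Mod(stats::fft(h$intensity))
  F[1L, 1L] <- 0
  peak <- which(F == max(F), arr.ind = TRUE)[1L, ]
  expect_identical(unname(peak), c(13L, 25L))   # 1-based bin indices

  h1 <- hologram_forward(p, noise_sd = 50, rng_seed = 42L)
  h2 <- hologram_forward(p, noise_sd = 50, rng_seed = 42L)
  expect_identical(h1$intensity, h2$intensity)
  h3 <- hologram_forward(p, noise_sd = 50, rng_seed = 43L)
  expect_false(identical(h1$intensity, h3$intensity))

  expect_error(hologram_forward(p, carrier = c(0.01, 0.01)), "carrier")
  expect_error(hologram_forward(p, carrier = c(0.4, 0.4)), "carrier")
})

test_that("population sampling is seeded and realizes the class contrasts", {
  s1 <- sample_population(1L, rng_seed = 9L)
  s2 <- sample_population(1L, rng_seed = 9L)
  expect_identical(s1, s2)

  # truth-level contrasts over a 10-seed sweep
  for (seed in 1:10) {
    specs <- sample_population(200L, rng_seed = seed)
    tr <- do.call(rbind, lapply(specs, function(s) {
      tt <- phantom_truth(s)
      data.frame(class = s$cell_class, ov = tt$ov_rad_um2,
                 d75 = tt$delta_75_um)
    }))
    h <- tr[tr$class == "healthy", ]; t <- tr[tr$class == "thal", ]
    se_ov <- sqrt(var(h$ov) / nrow(h) + var(t$ov) / nrow(t))
    expect_lt(mean(t$ov), mean(h$ov) - 3 * se_ov)
    expect_gt(mean(t$d75), mean(h$d75))
  }
})

test_that("scene composition respects gaps, determinism and ground truth", {
  specs <- sample_population(3L, rng_seed = 2L)[1:5]
  sc <- compose_scene(specs, shape = c(420L, 420L), pixel_size = 0.08,
                      min_gap_px = 5, rng_seed = 6L)
  expect_identical(n_instances(sc$labels), 5L)
  ctrs <- t(vapply(sc$specs, `[[`, numeric(2L), "center"))
  radii <- vapply(sc$specs, `[[`, numeric(1L), "radius")
  for (i in 1:4) for (j in (i + 1):5) {
    gap_px <- (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) -
                 radii[i] - radii[j]) / 0.08
    expect_gte(gap_px, 5)
  }
  expect_identical(nrow(sc$features_true), 5L)
  expect_equal(sc$features_true$ov_rad_um2,
               2 * pi * vapply(sc$specs, `[[`, numeric(1L), "delta_n") /
                 0.532 * sc$features_true$volume_um3, tolerance = 1e-6)

  sc2 <- compose_scene(specs, shape = c(420L, 420L), pixel_size = 0.08,
                       min_gap_px = 5, rng_seed = 6L)
  expect_identical(sc$phase$phase, sc2$phase$phase)
  expect_identical(sc$labels$labels, sc2$labels$labels)

  empty <- compose_scene(list(), shape = c(128L, 128L), pixel_size = 0.08)
  expect_identical(n_instances(empty$labels), 0L)
  expect_identical(nrow(empty$features_true), 0L)

  expect_error(compose_scene(specs, shape = c(100L, 100L), pixel_size = 0.08),
               "canvas")
})

test_that("phantom truth values agree with independent quadrature", {
  spec <- phantom_spec(radius = 3.5, shape_coeffs = c(0.5, 8.5, -4.0),
                      delta_n = 0.055)
  tr <- phantom_truth(spec)
  f <- function(rho) 2 * pi * rho * sqrt(1 - rho^2) *
    (0.5 + 8.5 * rho^2 - 4.0 * rho^4)
  v_quad <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value * 3.5^2
  expect_equal(tr$volume_um3, v_quad, tolerance = 1e-8)
  expect_equal(tr$ov_rad_um2, 2 * pi * 0.055 / 0.532 * v_quad,
               tolerance = 1e-8)
})

test_that("hologram noise produces the documented reconstruction noise scale", {
  # flat scene, carrier on exact FFT bins, so the residual is noise alone
  p0 <- phase_map(matrix(0, 128, 128), 0.08, provenance = "synthetic")
  holo <- hologram_forward(p0, carrier = c(18 / 128, 32 / 128), rng_seed = 3L)
  pm <- reconstruct_phase(holo)
  expect_lt(sd(pm$phase), 0.02)
  expect_gt(sd(pm$phase), 0.005)
})
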