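#' Parametric red-blood-cell phantoms and hologram forward model
#'
#' Phantom cells use the Evans–Fung biconcave parameterization
#' `T(rho) = sqrt(1 - rho^2) * (c0 + c2 rho^2 + c4 rho^4)` with `rho = r/R`,
#' which covers both the healthy discocyte regime (classic coefficients
#' 0.81, 7.83, -4.39 um at R = 3.91 um, analytic volume 94.1 um^3) and
#' flatter, doughnut-trending thalassemic shapes (smaller `c0`, i.e. a deeper
#' central dimple, smaller radius and refractive-index contrast). Phase maps
#' follow the thin-object projection `phi = 2 pi dn T / lambda`, and off-axis
#' holograms add a carrier fringe, shot-like Gaussian camera noise and 16-bit
#' quantization.
#'
#' @name synth
NULL

#' Evaluate code with a locally seeded RNG
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' seeded stages do not disturb each other.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

evans_fung_poly <- function(rho, coeffs) {
  coeffs[1L] + coeffs[2L] * rho^2 + coeffs[3L] * rho^4
}

evans_fung_thickness <- function(rho, coeffs) {
  ifelse(rho < 1, sqrt(pmax(1 - rho^2, 0)) * evans_fung_poly(rho, coeffs), 0)
}

#' Specify a phantom cell
#'
#' @param cell_class `"healthy"` or `"thal"`.
#' @param radius cell radius R in micrometres.
#' @param shape_coeffs Evans–Fung coefficients `(c0, c2, c4)` in micrometres.
#' @param delta_n refractive-index contrast between cytoplasm and medium.
#' @param wavelength illumination wavelength in micrometres.
#' @param center cell centre `(x, y)` in micrometres (NA = canvas centre).
#' @param rotation in-plane rotation in degrees.
#' @return an object of class `PhantomSpec`. Specs whose thickness polynomial
#'   goes negative anywhere on the unit radius (checked at 1000 points) are
#'   rejected.
#' @export
phantom_spec <- function(cell_class = c("healthy", "thal"), radius = 3.91,
                         shape_coeffs = c(0.81, 7.83, -4.39), delta_n = 0.06,
                         wavelength = 0.532, center = c(NA_real_, NA_real_),
                         rotation = 0) {
  cell_class <- match.arg(cell_class)
  stopifnot(length(radius) == 1L, length(shape_coeffs) == 3L,
            length(delta_n) == 1L, length(wavelength) == 1L,
            length(center) == 2L, length(rotation) == 1L)
  if (radius <= 0) stop("radius must be positive")
  if (delta_n <= 0) stop("delta_n must be positive")
  if (wavelength <= 0) stop("wavelength must be positive")
  rho <- seq(0, 1, length.out = 1000L)
  if (any(evans_fung_poly(rho, shape_coeffs) < 0))
    stop("shape_coeffs yield negative thickness inside the cell; spec rejected")
  structure(list(cell_class = cell_class, radius = radius,
                 shape_coeffs = shape_coeffs, delta_n = delta_n,
                 wavelength = wavelength, center = center, rotation = rotation),
            class = "PhantomSpec")
}

#' Analytic ground-truth features of a phantom
#'
#' Closed-form/quadrature values used as oracles: volume from the radial
#' integral `2 pi R^2 int rho sqrt(1-rho^2) poly(rho) drho`, optical volume
#' `(2 pi dn / lambda) V`, central thickness `t_0` as the area-weighted mean
#' over `rho <= 0.1`, and `delta_75 = T(0.75) - t_0`.
#'
#' @param spec a [phantom_spec()].
#' @return named list with `volume_um3`, `ov_rad_um2`, `t_0_um`,
#'   `delta_75_um`, `t_peak_um`, `cell_class`.
#' @export
phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  cf <- spec$shape_coeffs
  # int_0^1 rho sqrt(1-rho^2) rho^{2k} drho = 1/3, 2/15, 8/105 for k = 0,1,2
  vol <- 2 * pi * spec$radius^2 *
    (cf[1L] / 3 + cf[2L] * 2 / 15 + cf[3L] * 8 / 105)
  ov <- 2 * pi * spec$delta_n / spec$wavelength * vol
  t0 <- stats::integrate(function(rho) 2 * pi * rho * evans_fung_thickness(rho, cf),
                         0, 0.1, rel.tol = 1e-10)$value / (pi * 0.1^2)
  t75 <- evans_fung_thickness(0.75, cf)
  tpk <- max(evans_fung_thickness(seq(0, 1, length.out = 2000L), cf))
  list(volume_um3 = vol, ov_rad_um2 = ov, t_0_um = t0,
       delta_75_um = t75 - t0, t_peak_um = tpk, cell_class = spec$cell_class)
}

#' Sample a phantom thickness map on a pixel grid
#'
#' @param spec a [phantom_spec()].
#' @param shape grid dimensions `c(rows, cols)`.
#' @param pixel_size micrometres per pixel; the grid must resolve the cell
#'   (at least 20 px across the diameter).
#' @return a [thickness_map()], 0 for `rho >= 1`.
#' @export
discocyte_thickness <- function(spec, shape, pixel_size) {
  stopifnot(inherits(spec, "PhantomSpec"), length(shape) == 2L, pixel_size > 0)
  if (2 * spec$radius / pixel_size < 20)
    stop("grid does not resolve the cell (< 20 px across the diameter)")
  m <- shape[1L]; n <- shape[2L]
  ctr <- spec$center
  if (any(is.na(ctr))) ctr <- c(n / 2, m / 2) * pixel_size
  x <- (seq_len(n) - 0.5) * pixel_size   # columns -> x
  y <- (seq_len(m) - 0.5) * pixel_size   # rows    -> y
  rho <- sqrt(outer((y - ctr[2L])^2, (x - ctr[1L])^2, `+`)) / spec$radius
  thickness_map(evans_fung_thickness(rho, spec$shape_coeffs), pixel_size)
}

#' Thin-object phase forward model
#'
#' `phi = 2 pi dn T / lambda`, zero outside the cell.
#'
#' @param t a [thickness_map()].
#' @param delta_n refractive-index contrast (> 0).
#' @param wavelength wavelength in micrometres (> 0).
#' @return a synthetic [phase_map()].
#' @export
phase_forward <- function(t, delta_n, wavelength) {
  stopifnot(inherits(t, "ThicknessMap"))
  if (delta_n <= 0) stop("delta_n must be positive")
  if (wavelength <= 0) stop("wavelength must be positive")
  phase_map(2 * pi * delta_n * t$thickness / wavelength, t$pixel_size,
            provenance = "synthetic")
}

#' Synthesize an off-axis hologram from a phase map
#'
#' `I = I0 |1 + m exp(i(phi + 2 pi f . r))|^2` plus seeded Gaussian noise,
#' clipped at 0 and quantized to 16-bit counts.
#'
#' @param p a [phase_map()].
#' @param carrier length-2 carrier frequency (row, col) in cycles/pixel;
#'   its magnitude must lie in (0.05, 0.45) so the sideband separates from DC.
#' @param fringe_contrast modulation depth m in (0, 1].
#' @param noise_sd Gaussian camera-noise standard deviation in counts; the
#'   default 540 produces about 0.01 rad of reconstruction phase noise at the
#'   default beam intensity (pass 0 for noise-free oracle holograms).
#' @param rng_seed integer seed for the noise draw.
#' @param wavelength wavelength (um) recorded on the output.
#' @param i0 mean beam intensity in counts.
#' @return an [interferogram()] whose `carrier_hint` records the true carrier.
#' @export
hologram_forward <- function(p, carrier = c(0.14, 0.25), fringe_contrast = 0.8,
                             noise_sd = 540, rng_seed = 1L, wavelength = 0.532,
                             i0 = 12000) {
  stopifnot(inherits(p, "PhaseMap"), length(carrier) == 2L)
  cmag <- sqrt(sum(carrier^2))
  if (cmag <= 0.05 || cmag >= 0.45)
    stop("carrier magnitude must lie in (0.05, 0.45) cycles/px so the sideband separates from DC and stays below Nyquist")
  if (fringe_contrast <= 0 || fringe_contrast > 1)
    stop("fringe_contrast must lie in (0, 1]")
  m <- nrow(p$phase); n <- ncol(p$phase)
  ramp <- 2 * pi * (outer((0:(m - 1L)) * carrier[1L], (0:(n - 1L)) * carrier[2L], `+`))
  I <- i0 * (1 + fringe_contrast^2 +
             2 * fringe_contrast * cos(p$phase + ramp))
  if (noise_sd > 0)
    I <- I + with_seed(rng_seed, matrix(stats::rnorm(m * n, 0, noise_sd), m, n))
  I <- pmin(pmax(round(I), 0), 65535)
  interferogram(I, p$pixel_size, wavelength, carrier_hint = carrier)
}

#' Default per-class phantom parameter distributions
#'
#' Normal means/SDs for radius, Evans–Fung coefficients and refractive-index
#' contrast. The healthy class centres on the classic discocyte
#' (R 3.91 um, coefficients 0.81/7.83/-4.39 um, dn 0.060); the thalassemic
#' class is hypochromic with a deeper central dimple (doughnut trend):
#' R 3.80 um, coefficients 0.28/9.6/-5.2 um, dn 0.055. Within-class spreads
#' emulate biological diversity; the between-class shifts sit mostly on
#' hemoglobin contrast and dimple depth, the axes that drive the phase-shift
#' statistics.
#'
#' @return nested list of class parameter distributions.
#' @export
default_class_params <- function() {
  list(
    healthy = list(radius = c(3.91, 0.30), c0 = c(0.81, 0.16),
                   c2 = c(7.83, 0.30), c4 = c(-4.39, 0.25),
                   delta_n = c(0.060, 0.004)),
    thal    = list(radius = c(3.80, 0.30), c0 = c(0.28, 0.11),
                   c2 = c(9.60, 0.30), c4 = c(-5.20, 0.25),
                   delta_n = c(0.055, 0.004))
  )
}

#' Draw a phantom population
#'
#' @param n_per_class integer count per class (named or length 1/2).
#' @param class_params distributions as from [default_class_params()].
#' @param rng_seed integer seed.
#' @param wavelength wavelength (um) shared by all specs.
#' @return list of [phantom_spec()]; specs failing the thickness
#'   non-negativity check are resampled.
#' @export
sample_population <- function(n_per_class, class_params = default_class_params(),
                              rng_seed = 1L, wavelength = 0.532) {
  if (length(n_per_class) == 1L)
    n_per_class <- c(healthy = n_per_class, thal = n_per_class)
  stopifnot(all(n_per_class >= 1L))
  with_seed(rng_seed, {
    specs <- list()
    for (cl in names(class_params)) {
      nc <- n_per_class[[cl]]
      if (is.null(nc) || nc < 1) next
      pp <- class_params[[cl]]
      for (i in seq_len(nc)) {
        repeat {
          s <- try(phantom_spec(
            cell_class = cl,
            radius = max(stats::rnorm(1, pp$radius[1L], pp$radius[2L]), 1),
            shape_coeffs = c(stats::rnorm(1, pp$c0[1L], pp$c0[2L]),
                             stats::rnorm(1, pp$c2[1L], pp$c2[2L]),
                             stats::rnorm(1, pp$c4[1L], pp$c4[2L])),
            delta_n = max(stats::rnorm(1, pp$delta_n[1L], pp$delta_n[2L]), 1e-3),
            wavelength = wavelength,
            rotation = stats::runif(1, 0, 360)), silent = TRUE)
          if (!inherits(s, "try-error")) break
        }
        specs[[length(specs) + 1L]] <- s
      }
    }
    specs
  })
}

# smooth unit-mean multiplicative field emulating hemoglobin-concentration
# inhomogeneity: Gaussian-filtered white noise, identical statistics in all
# classes, so it adds realistic within-class texture variance without class
# information
hb_inhomogeneity_field <- function(shape, pixel_size, sd = 0.04,
                                   corr_um = 0.6, rng_seed = 1L) {
  if (sd <= 0) return(matrix(1, shape[1L], shape[2L]))
  w <- with_seed(rng_seed,
                 matrix(stats::rnorm(shape[1L] * shape[2L]), shape[1L], shape[2L]))
  f <- EBImage::imageData(EBImage::gblur(EBImage::Image(w),
                                         sigma = corr_um / pixel_size))
  f <- f / stats::sd(f) * sd
  1 + f - mean(f)
}

#' Render a single phantom on its own canvas
#'
#' Optionally applies two realism perturbations: a smooth multiplicative
#' hemoglobin-inhomogeneity field on the phase (identical statistics in both
#' classes) and additive Gaussian phase noise emulating reconstruction noise.
#'
#' @param spec a [phantom_spec()].
#' @param pixel_size micrometres per pixel.
#' @param pad_um background margin around the cell.
#' @param phase_noise_sd additive phase noise SD in radians (0 = clean).
#' @param texture_sd relative SD of the hemoglobin-inhomogeneity field
#'   (0 = uniform hemoglobin).
#' @param texture_corr_um correlation length of the inhomogeneity field.
#' @param rng_seed seed for both perturbations.
#' @return list with `thickness` ([thickness_map()]), `phase` ([phase_map()]),
#'   `mask` (logical support) and `truth` ([phantom_truth()]). Truth values
#'   refer to the clean phantom.
#' @export
render_phantom <- function(spec, pixel_size = 0.08, pad_um = 2,
                           phase_noise_sd = 0, texture_sd = 0,
                           texture_corr_um = 0.6, rng_seed = 1L) {
  side <- ceiling(2 * (spec$radius + pad_um) / pixel_size)
  t <- discocyte_thickness(spec, c(side, side), pixel_size)
  p <- phase_forward(t, spec$delta_n, spec$wavelength)
  if (texture_sd > 0) {
    fld <- hb_inhomogeneity_field(dim(p$phase), pixel_size, sd = texture_sd,
                                  corr_um = texture_corr_um,
                                  rng_seed = rng_seed)
    p$phase <- p$phase * fld
  }
  if (phase_noise_sd > 0) {
    p$phase <- p$phase + with_seed(rng_seed + 1L,
      matrix(stats::rnorm(length(p$phase), 0, phase_noise_sd),
             nrow(p$phase), ncol(p$phase)))
  }
  list(thickness = t, phase = p, mask = t$mask, truth = phantom_truth(spec))
}

#' Compose a multi-cell scene with ground truth
#'
#' Cells are placed by rejection sampling (up to 1000 tries per cell) so that
#' the gap between any two supports is at least `min_gap_px` pixels (negative
#' values allow controlled overlap). Phases superpose (thin-object
#' approximation); overlap pixels are labelled by the nearest cell centre.
#'
#' @param specs list of [phantom_spec()].
#' @param shape canvas `c(rows, cols)` in pixels.
#' @param pixel_size micrometres per pixel.
#' @param min_gap_px minimum support gap in pixels.
#' @param rng_seed integer placement seed.
#' @return a `SceneTruth` list: `phase`, `labels`, `thickness` (per-cell
#'   [thickness_map()] list), `features_true` (data frame with analytic ov,
#'   volume, t_0, delta_75 and class per cell).
#' @export
compose_scene <- function(specs, shape = c(256L, 256L), pixel_size = 0.08,
                          min_gap_px = 5, rng_seed = 1L) {
  m <- shape[1L]; n <- shape[2L]
  placed <- list()
  with_seed(rng_seed, {
    for (k in seq_along(specs)) {
      s <- specs[[k]]
      rpx <- s$radius / pixel_size
      lo_x <- (rpx + 2) * pixel_size; hi_x <- (n - rpx - 2) * pixel_size
      lo_y <- (rpx + 2) * pixel_size; hi_y <- (m - rpx - 2) * pixel_size
      if (lo_x >= hi_x || lo_y >= hi_y)
        stop("canvas too small for the requested cells; use a larger canvas")
      ok <- FALSE
      for (try_i in seq_len(1000L)) {
        ctr <- c(stats::runif(1, lo_x, hi_x), stats::runif(1, lo_y, hi_y))
        clear <- TRUE
        for (p0 in placed) {
          d_px <- sqrt(sum((ctr - p0$center)^2)) / pixel_size
          need <- (s$radius + p0$radius) / pixel_size + min_gap_px
          if (d_px < need) { clear <- FALSE; break }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("could not place cell %d after 1000 tries; use a larger canvas", k))
      s$center <- ctr
      placed[[k]] <- s
    }
  })

  phase <- matrix(0, m, n)
  labels <- matrix(0L, m, n)
  bestd <- matrix(Inf, m, n)
  thick <- vector("list", length(placed))
  truth <- vector("list", length(placed))
  for (k in seq_along(placed)) {
    s <- placed[[k]]
    t <- discocyte_thickness(s, c(m, n), pixel_size)
    thick[[k]] <- t
    phase <- phase + phase_forward(t, s$delta_n, s$wavelength)$phase
    x <- (seq_len(n) - 0.5) * pixel_size
    y <- (seq_len(m) - 0.5) * pixel_size
    d <- sqrt(outer((y - s$center[2L])^2, (x - s$center[1L])^2, `+`))
    take <- t$mask & d < bestd
    labels[take] <- k
    bestd[take] <- d[take]
    tr <- phantom_truth(s)
    truth[[k]] <- data.frame(cell_id = k, class = s$cell_class,
                             ov_rad_um2 = tr$ov_rad_um2,
                             volume_um3 = tr$volume_um3,
                             t_0_um = tr$t_0_um,
                             delta_75_um = tr$delta_75_um)
  }
  features_true <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cell_id = integer(), class = character(), ov_rad_um2 = numeric(),
               volume_um3 = numeric(), t_0_um = numeric(), delta_75_um = numeric())
  list(phase = phase_map(phase, pixel_size, provenance = "synthetic"),
       labels = label_map(labels, pixel_size),
       thickness = thick,
       features_true = features_true,
       specs = placed)
}
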