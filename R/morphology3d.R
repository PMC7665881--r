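#' 3-D morphological features from thickness maps
#'
#' Six descriptors of single-cell 3-D shape computed from a height-field
#' thickness map: volume V, surface-area-to-volume ratio S/V, sphericity
#' index `SI = pi^(1/3) (6V)^(2/3) / S`, average thickness Tavg, central
#' thickness T0, and `delta75`, the azimuthally averaged thickness at 75% of
#' the normalized cell radius minus T0 (positive for doughnut-shaped cells).
#' Thickness follows from phase under the constant-refractive-index
#' assumption `T = lambda phi / (2 pi dn)`. The cell is modelled as
#' mirror-symmetric about its midplane, so the surface is twice the upper
#' height field `T/2` integrated with central-difference gradients.
#'
#' @name morphology3d
NULL

#' Convert a phase map to a thickness map
#'
#' `T = lambda * phi / (2 pi dn)` inside the mask, clipped at 0, zero outside.
#'
#' @param p a [phase_map()].
#' @param mask logical cell support.
#' @param delta_n refractive-index contrast (> 0); default 0.06 is a typical
#'   hemoglobin-vs-medium value and is a configuration choice, not a
#'   universal constant.
#' @param wavelength wavelength in micrometres (> 0).
#' @return a [thickness_map()].
#' @export
thickness_from_phase <- function(p, mask, delta_n = 0.06, wavelength = 0.532) {
  stopifnot(inherits(p, "PhaseMap"), is.logical(mask),
            identical(dim(mask), dim(p$phase)))
  if (delta_n <= 0) stop("delta_n must be positive")
  if (wavelength <= 0) stop("wavelength must be positive")
  t <- matrix(0, nrow(p$phase), ncol(p$phase))
  t[mask] <- pmax(wavelength * p$phase[mask] / (2 * pi * delta_n), 0)
  thickness_map(t, p$pixel_size, mask = mask | (t > 0))
}

#' Volume and surface area of a cell thickness map
#'
#' `V = sum(T) * pixel_area`; the surface is the mirror-symmetric height
#' field: `S = 2 * sum over mask sqrt(1 + |grad(T/2)|^2) * pixel_area` with
#' central-difference gradients.
#'
#' @param t a [thickness_map()] with non-empty mask.
#' @return named list `volume` (um^3) and `surface_area` (um^2).
#' @export
volume_and_surface <- function(t) {
  stopifnot(inherits(t, "ThicknessMap"))
  if (!any(t$mask)) stop("mask is empty")
  ps <- t$pixel_size
  h <- t$thickness / 2
  m <- nrow(h); n <- ncol(h)
  gx <- matrix(0, m, n); gy <- matrix(0, m, n)
  gx[2:(m - 1L), ] <- (h[3:m, ] - h[1:(m - 2L), ]) / (2 * ps)
  gx[1L, ] <- (h[2L, ] - h[1L, ]) / ps
  gx[m, ] <- (h[m, ] - h[m - 1L, ]) / ps
  gy[, 2:(n - 1L)] <- (h[, 3:n] - h[, 1:(n - 2L)]) / (2 * ps)
  gy[, 1L] <- (h[, 2L] - h[, 1L]) / ps
  gy[, n] <- (h[, n] - h[, n - 1L]) / ps
  el <- sqrt(1 + gx^2 + gy^2)
  list(volume = sum(t$thickness) * ps^2,
       surface_area = 2 * sum(el[t$mask]) * ps^2)
}

#' Sphericity index
#'
#' `SI = pi^(1/3) * (6 V)^(2/3) / S`; 1 for a sphere, below 1 for flattened
#' or biconcave shapes.
#'
#' @param volume volume in um^3 (> 0).
#' @param surface_area surface area in um^2 (> 0).
#' @return dimensionless sphericity.
#' @export
sphericity <- function(volume, surface_area) {
  if (any(volume <= 0) || any(surface_area <= 0))
    stop("volume and surface_area must be positive")
  pi^(1 / 3) * (6 * volume)^(2 / 3) / surface_area
}

# bilinear sample of matrix at fractional (row, col) positions
bilinear_at <- function(img, rr, cc) {
  m <- nrow(img); n <- ncol(img)
  rr <- pmin(pmax(rr, 1), m); cc <- pmin(pmax(cc, 1), n)
  r0 <- pmin(floor(rr), m - 1L); c0 <- pmin(floor(cc), n - 1L)
  fr <- rr - r0; fc <- cc - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    img[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    img[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Thickness-profile features Tavg, T0 and delta75
#'
#' `t_avg = V / projected area`. The radial coordinate is normalized by the
#' equivalent-disc radius `R_eq = sqrt(area / pi)` about the mask centroid.
#' `t_0` is the mean thickness within `rho <= 0.1` (a small central average,
#' robust to noise, rather than a single-pixel read). The azimuthally
#' averaged profile uses 64 angular bins with bilinear radial interpolation;
#' `delta_75 = Tbar(0.75) - t_0`, positive for doughnut shapes.
#'
#' @param t a [thickness_map()]; masks under `min_px` pixels return `NA`
#'   profile features with `degenerate = TRUE`.
#' @param min_px minimum mask size for profile estimation.
#' @param n_angles number of azimuthal bins.
#' @return named list `t_avg`, `t_0`, `delta_75`, `degenerate`.
#' @export
thickness_profile_features <- function(t, min_px = 50L, n_angles = 64L) {
  stopifnot(inherits(t, "ThicknessMap"))
  npx <- sum(t$mask)
  if (npx == 0L) stop("mask is empty")
  ps <- t$pixel_size
  area <- npx * ps^2
  vol <- sum(t$thickness) * ps^2
  t_avg <- vol / area
  if (npx < min_px)
    return(list(t_avg = t_avg, t_0 = NA_real_, delta_75 = NA_real_,
                degenerate = TRUE))
  idx <- which(t$mask, arr.ind = TRUE)
  ctr <- colMeans(idx)                  # centroid in pixel coordinates
  r_eq <- sqrt(area / pi) / ps          # equivalent radius in px
  rho <- sqrt((idx[, 1L] - ctr[1L])^2 + (idx[, 2L] - ctr[2L])^2) / r_eq
  central <- rho <= 0.1
  t_0 <- if (any(central)) mean(t$thickness[t$mask][central]) else
    bilinear_at(t$thickness, ctr[1L], ctr[2L])
  th <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  rr <- ctr[1L] + 0.75 * r_eq * cos(th)
  cc <- ctr[2L] + 0.75 * r_eq * sin(th)
  t_75 <- mean(bilinear_at(t$thickness, rr, cc))
  list(t_avg = t_avg, t_0 = t_0, delta_75 = t_75 - t_0, degenerate = FALSE)
}

#' Names of the six 3-D feature columns
#' @return character vector of length 7 (six features plus `sv_ratio`'s
#'   companions): `volume_um3`, `surface_um2`, `sv_ratio_per_um`,
#'   `sphericity`, `t_avg_um`, `t_0_um`, `delta_75_um`.
#' @export
feature_columns_3d <- function() {
  c("volume_um3", "surface_um2", "sv_ratio_per_um", "sphericity",
    "t_avg_um", "t_0_um", "delta_75_um")
}

#' All six 3-D features for every cell in a labelled scene
#'
#' @param thickness a [thickness_map()] covering the scene, or a phase map
#'   plus optics via [thickness_from_phase()] upstream.
#' @param labels a [label_map()]; each instance is analysed on its own
#'   support.
#' @return data frame, one row per instance, columns `cell_id` +
#'   [feature_columns_3d()].
#' @export
extract_features_3d <- function(thickness, labels) {
  stopifnot(inherits(thickness, "ThicknessMap"), inherits(labels, "LabelMap"),
            identical(dim(thickness$thickness), dim(labels$labels)))
  N <- n_instances(labels)
  rows <- list()
  for (k in seq_len(N)) {
    mask <- labels$labels == k
    tk <- thickness$thickness
    tk[!mask] <- 0
    tmk <- thickness_map(tk, thickness$pixel_size, mask = mask & (tk > 0))
    if (!any(tmk$mask)) next
    vs <- volume_and_surface(tmk)
    pf <- thickness_profile_features(tmk)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = k,
      volume_um3 = vs$volume, surface_um2 = vs$surface_area,
      sv_ratio_per_um = vs$surface_area / vs$volume,
      sphericity = sphericity(vs$volume, vs$surface_area),
      t_avg_um = pf$t_avg, t_0_um = pf$t_0, delta_75_um = pf$delta_75)
  }
  if (!length(rows)) {
    return(as.data.frame(stats::setNames(
      c(list(integer()), rep(list(numeric()), 7L)),
      c("cell_id", feature_columns_3d()))))
  }
  do.call(rbind, rows)
}
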