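#' Single-cell 2-D feature extraction
#'
#' The 15-feature quantification scheme: five phase-shift statistics
#' (optical volume, mean, 5th and 95th percentile, standard deviation), five
#' 2-D morphological descriptors (projected area, perimeter, major/minor
#' axis length, eccentricity) and five gray-level co-occurrence texture
#' statistics (contrast, dissimilarity, homogeneity, energy, angular second
#' moment) per segmented cell.
#'
#' @name features2d
NULL

#' Names of the 15 per-cell 2-D feature columns
#' @return character vector of length 15.
#' @export
feature_columns_2d <- function() {
  c("ov_rad_um2", "phase_mean_rad", "phase_p5_rad", "phase_p95_rad",
    "phase_sd_rad", "area_um2", "perimeter_um", "major_axis_um",
    "minor_axis_um", "eccentricity", "glcm_contrast", "glcm_dissimilarity",
    "glcm_homogeneity", "glcm_energy", "glcm_asm")
}

#' Phase-shift statistics of one cell
#'
#' Optical volume is the phase integral over the cell,
#' `ov = sum(phi) * pixel_area` (rad um^2). Percentiles use linear
#' interpolation between order statistics; the standard deviation is the
#' population SD (a per-cell descriptor, not an estimator).
#'
#' @param p a [phase_map()].
#' @param mask logical matrix, the cell support (non-empty, same shape).
#' @return named list `ov`, `phase_mean`, `phase_p5`, `phase_p95`,
#'   `phase_sd`, plus `degenerate = TRUE` when the mask has fewer than 20 px.
#' @export
phase_statistics <- function(p, mask) {
  stopifnot(inherits(p, "PhaseMap"), is.logical(mask),
            identical(dim(mask), dim(p$phase)))
  if (!any(mask)) stop("mask is empty")
  v <- p$phase[mask]
  pa <- p$pixel_size^2
  qs <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
  list(ov = sum(v) * pa,
       phase_mean = mean(v),
       phase_p5 = qs[1L],
       phase_p95 = qs[2L],
       phase_sd = sqrt(mean((v - mean(v))^2)),
       degenerate = length(v) < 20L)
}

# total marching-squares contour length (px) of the 0.5-level isoline.
# Contouring the raw binary mask overestimates smooth boundaries by ~7%
# (staircase corners), so the indicator is Gaussian-smoothed (sigma px)
# first; tiny masks whose smoothed peak falls below 0.5 fall back to the
# raw binary contour.
marching_squares_perimeter <- function(mask, sigma = 1.5) {
  pad <- 4L
  z <- matrix(0, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
  z[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask * 1
  ring_length <- function(zz) {
    cl <- grDevices::contourLines(seq_len(nrow(zz)), seq_len(ncol(zz)), zz,
                                  levels = 0.5)
    if (!length(cl)) return(0)
    sum(vapply(cl, function(cc) {
      x <- c(cc$x, cc$x[1L]); y <- c(cc$y, cc$y[1L])
      sum(sqrt(diff(x)^2 + diff(y)^2))
    }, numeric(1L)))
  }
  zs <- EBImage::imageData(EBImage::gblur(EBImage::Image(z), sigma = sigma))
  out <- ring_length(zs)
  if (out == 0) out <- ring_length(z)
  out
}

#' 2-D morphological descriptors of one cell mask
#'
#' Area is pixel count times pixel area; perimeter is the marching-squares
#' contour length at the 0.5 level of a Gaussian-smoothed (sigma 1.5 px) mask
#' indicator, which tracks the sub-pixel boundary without staircase bias;
#' axis lengths come from the ellipse with
#' the same normalized second central moments (`4 * sqrt(eigenvalue)` of the
#' coordinate covariance); `eccentricity = sqrt(1 - (minor/major)^2)`.
#'
#' @param mask logical matrix, a single 4-connected component.
#' @param pixel_size micrometres per pixel.
#' @return named list `area`, `perimeter`, `major_axis`, `minor_axis`,
#'   `eccentricity` (+ `degenerate` for masks under 20 px).
#' @export
morphology2d <- function(mask, pixel_size) {
  stopifnot(is.logical(mask), pixel_size > 0)
  npx <- sum(mask)
  if (npx == 0L) stop("mask is empty")
  ncomp <- max(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (ncomp > 1L)
    stop(sprintf("mask has %d connected components; expected 1", ncomp))
  area <- npx * pixel_size^2
  perim <- marching_squares_perimeter(mask) * pixel_size
  idx <- which(mask, arr.ind = TRUE)
  if (npx == 1L) {
    major <- minor <- 0; ecc <- 0
  } else {
    ctr <- colMeans(idx)
    d <- sweep(idx, 2L, ctr)
    C <- crossprod(d) / npx
    ev <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev[ev < 0] <- 0
    major <- 4 * sqrt(ev[1L]) * pixel_size
    minor <- 4 * sqrt(ev[2L]) * pixel_size
    ecc <- if (major > 0) sqrt(max(1 - (minor / major)^2, 0)) else 0
  }
  list(area = area, perimeter = perim, major_axis = major, minor_axis = minor,
       eccentricity = ecc, degenerate = npx < 20L)
}

glcm_offsets <- function(distance_px) {
  list(`0` = c(0L, distance_px), `45` = c(-distance_px, distance_px),
       `90` = c(-distance_px, 0L), `135` = c(-distance_px, -distance_px))
}

#' Gray-level co-occurrence texture features of one cell
#'
#' In-mask phase is linearly quantized to `levels` gray levels between the
#' in-mask minimum and maximum; co-occurrences are counted only for pixel
#' pairs both inside the mask, symmetrized and normalized per angle, and the
#' five Haralick statistics are averaged over the angle set.
#'
#' @param p a [phase_map()].
#' @param mask logical cell support (at least 2 px).
#' @param levels number of gray levels (>= 2).
#' @param distance_px co-occurrence offset in pixels.
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @return named list `contrast`, `dissimilarity`, `homogeneity`, `energy`,
#'   `asm` (+ `constant = TRUE` for a constant in-mask image, which returns
#'   contrast 0, dissimilarity 0, homogeneity 1, energy 1, asm 1).
#' @export
glcm_features <- function(p, mask, levels = 32L, distance_px = 1L,
                          angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(p, "PhaseMap"), is.logical(mask),
            identical(dim(mask), dim(p$phase)))
  if (sum(mask) < 2L) stop("mask must contain at least 2 pixels")
  if (levels < 2L) stop("levels must be >= 2")
  stopifnot(all(angles %in% c(0, 45, 90, 135)))

  v <- p$phase
  vin <- v[mask]
  lo <- min(vin); hi <- max(vin)
  constant <- hi <= lo
  q <- matrix(0L, nrow(v), ncol(v))
  if (!constant) {
    qq <- floor((v - lo) / (hi - lo) * levels)
    qq[qq >= levels] <- levels - 1L
    qq[qq < 0L] <- 0L
    q[] <- as.integer(qq)
  }

  m <- nrow(v); n <- ncol(v)
  offs <- glcm_offsets(as.integer(distance_px))[as.character(angles)]
  per_angle <- lapply(offs, function(o) {
    dr <- o[1L]; dc <- o[2L]
    r1 <- max(1L, 1L - dr):min(m, m - dr)
    c1 <- max(1L, 1L - dc):min(n, n - dc)
    a_mask <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(a_mask)) return(NULL)
    qa <- q[r1, c1, drop = FALSE][a_mask]
    qb <- q[r1 + dr, c1 + dc, drop = FALSE][a_mask]
    counts <- tabulate(qa * levels + qb + 1L, nbins = levels * levels)
    P <- matrix(counts, levels, levels, byrow = TRUE)  # row = qa, col = qb
    P <- P + t(P)
    P <- P / sum(P)
    i <- row(P) - 1L; j <- col(P) - 1L
    c(contrast = sum(P * (i - j)^2),
      dissimilarity = sum(P * abs(i - j)),
      homogeneity = sum(P / (1 + (i - j)^2)),
      asm = sum(P^2))
  })
  per_angle <- per_angle[!vapply(per_angle, is.null, logical(1L))]
  if (!length(per_angle)) stop("no in-mask pixel pairs at the requested offset")
  f <- colMeans(do.call(rbind, per_angle))
  out <- as.list(f)
  out$energy <- sqrt(out$asm)   # defined on the angle-averaged asm so the
  out$constant <- constant      # energy^2 = asm identity holds exactly
  out
}

#' Extract the 15-feature table for every cell in a scene
#'
#' One row per instance: `cell_id`, optional `class`, then the 15 features of
#' [feature_columns_2d()]. Border-touching cells are excluded (count
#' reported in a message); instances whose mask splits into several
#' 4-connected fragments keep only the largest fragment.
#'
#' @param p a [phase_map()].
#' @param labels a [label_map()] of identical shape.
#' @param class optional class label (length 1 or one per instance).
#' @param glcm_levels,glcm_distance,glcm_angles texture parameters passed to
#'   [glcm_features()].
#' @return data frame with 17 columns (`cell_id`, `class`, 15 features);
#'   zero rows when the label map is empty.
#' @export
extract_features <- function(p, labels, class = NA_character_,
                             glcm_levels = 32L, glcm_distance = 1L,
                             glcm_angles = c(0, 45, 90, 135)) {
  stopifnot(inherits(p, "PhaseMap"), inherits(labels, "LabelMap"),
            identical(dim(p$phase), dim(labels$labels)))
  N <- n_instances(labels)
  cls <- rep_len(as.character(class), max(N, 1L))
  rows <- list()
  n_border <- 0L
  lab <- labels$labels
  m <- nrow(lab); n <- ncol(lab)
  for (k in seq_len(N)) {
    mask <- lab == k
    if (any(mask[1L, ]) || any(mask[m, ]) || any(mask[, 1L]) || any(mask[, n])) {
      n_border <- n_border + 1L
      next
    }
    comp <- EBImage::bwlabel(EBImage::Image(mask * 1))
    if (max(comp) > 1L) {  # keep the largest fragment
      sizes <- tabulate(comp[comp > 0])
      mask <- matrix(as.integer(EBImage::imageData(comp)), m, n) == which.max(sizes)
    }
    ps <- phase_statistics(p, mask)
    mo <- morphology2d(mask, p$pixel_size)
    gl <- glcm_features(p, mask, levels = glcm_levels,
                        distance_px = glcm_distance, angles = glcm_angles)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = k, class = cls[k],
      ov_rad_um2 = ps$ov, phase_mean_rad = ps$phase_mean,
      phase_p5_rad = ps$phase_p5, phase_p95_rad = ps$phase_p95,
      phase_sd_rad = ps$phase_sd,
      area_um2 = mo$area, perimeter_um = mo$perimeter,
      major_axis_um = mo$major_axis, minor_axis_um = mo$minor_axis,
      eccentricity = mo$eccentricity,
      glcm_contrast = gl$contrast, glcm_dissimilarity = gl$dissimilarity,
      glcm_homogeneity = gl$homogeneity, glcm_energy = gl$energy,
      glcm_asm = gl$asm)
  }
  if (n_border > 0L)
    message(sprintf("extract_features: excluded %d border-touching cell(s)", n_border))
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      c(list(integer(), character()), rep(list(numeric()), 15L)),
      c("cell_id", "class", feature_columns_2d())))
    return(out)
  }
  do.call(rbind, rows)
}
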