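#' Off-axis hologram phase reconstruction
#'
#' The reconstruction chain is the standard single-shot off-axis recipe:
#' isolate the object sideband by bandpass filtering in the spatial-frequency
#' domain, inverse Fourier transform (no zero-padding; transforms run at the
#' native image size), take the argument of the demodulated complex field,
#' unwrap it with the least-squares discrete-cosine-transform solver, and
#' reference the background to zero with a fitted plane.
#'
#' @name holography
NULL

#' Wrap phase values to the principal branch (-pi, pi]
#'
#' @param x numeric vector or matrix of phase values in radians.
#' @return same shape, wrapped modulo 2 pi into (-pi, pi].
#' @export
wrap_phase <- function(x) {
  out <- atan2(sin(x), cos(x))
  out[out == -pi] <- pi
  out
}

# wrapped frequency-bin offset of each FFT bin (0-based, aliased to +/- n/2)
fft_freq_bins <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k > n / 2, k - n, k)
}

#' Demodulate the object sideband of an off-axis interferogram
#'
#' Finds the carrier peak in the intensity spectrum (largest peak outside a
#' 4-bin DC-exclusion disc, restricted to the positive-column-frequency half
#' plane unless a hint is given), applies a circular bandpass of radius
#' `radius_fraction` times the carrier distance, re-centres the sideband at
#' DC and inverse transforms.
#'
#' @param holo an [interferogram()].
#' @param carrier_hint length-2 carrier frequency in cycles/pixel (row, col);
#'   overrides the hint stored in `holo`. `NULL` auto-detects.
#' @param radius_fraction bandpass radius as a fraction of the carrier
#'   distance, in (0, 0.5].
#' @return complex matrix of the demodulated field, same size as the input,
#'   with attributes `carrier_bins` (detected peak, frequency bins) and
#'   `carrier_cpp` (cycles/pixel).
#' @export
extract_sideband <- function(holo, carrier_hint = NULL, radius_fraction = 0.5) {
  stopifnot(inherits(holo, "Interferogram"))
  if (!is.numeric(radius_fraction) || length(radius_fraction) != 1L ||
      radius_fraction <= 0 || radius_fraction > 0.5)
    stop("radius_fraction must lie in (0, 0.5]")
  if (is.null(carrier_hint)) carrier_hint <- holo$carrier_hint

  I <- holo$intensity
  m <- nrow(I); n <- ncol(I)
  F <- stats::fft(I)
  mag <- Mod(F)
  fr <- fft_freq_bins(m)            # row-frequency bins
  fc <- fft_freq_bins(n)            # column-frequency bins
  rr <- matrix(fr, m, n)
  cc <- matrix(fc, m, n, byrow = TRUE)
  dist_dc <- sqrt(rr^2 + cc^2)
  off_dc <- dist_dc > 4

  if (is.null(carrier_hint)) {
    search <- off_dc & (cc > 0 | (cc == 0 & rr > 0))
    med <- stats::median(mag[off_dc])
    peak_idx <- which(search)[which.max(mag[search])]
    snr <- mag[peak_idx] / med   # Inf = perfect peak over a silent spectrum
    if (is.nan(snr) || snr < 3)
      stop(sprintf("no detectable off-DC carrier peak (spectral SNR %.2f < 3)", snr))
  } else {
    target_r <- carrier_hint[1L] * m
    target_c <- carrier_hint[2L] * n
    near <- off_dc & abs(rr - target_r) <= 3 & abs(cc - target_c) <= 3
    if (!any(near)) stop("carrier_hint is outside the representable band")
    peak_idx <- which(near)[which.max(mag[near])]
  }
  pr <- rr[peak_idx]; pc <- cc[peak_idx]
  carrier_dist <- sqrt(pr^2 + pc^2)

  radius <- radius_fraction * carrier_dist
  bp <- sqrt((rr - pr)^2 + (cc - pc)^2) <= radius
  Ff <- F * bp
  # circular shift so the carrier bin lands on DC
  Ff <- Ff[((seq_len(m) - 1L + (pr %% m)) %% m) + 1L,
           ((seq_len(n) - 1L + (pc %% n)) %% n) + 1L, drop = FALSE]
  field <- stats::fft(Ff, inverse = TRUE) / (m * n)
  attr(field, "carrier_bins") <- c(pr, pc)
  attr(field, "carrier_cpp") <- c(pr / m, pc / n)
  field
}

#' Wrapped phase of a complex field
#'
#' @param field complex matrix (demodulated sideband).
#' @return a [wrapped_phase_map()] on the principal branch (-pi, pi];
#'   zero-magnitude pixels are set to 0 and counted in a message.
#' @export
wrapped_phase <- function(field) {
  stopifnot(is.matrix(field))
  if (!all(is.finite(Re(field))) || !all(is.finite(Im(field))))
    stop("field must be finite")
  if (all(Mod(field) == 0)) stop("field is identically zero")
  zero <- Mod(field) == 0
  ph <- atan2(Im(field), Re(field))
  ph[ph == -pi] <- pi
  if (any(zero)) {
    ph[zero] <- 0
    message(sprintf("wrapped_phase: %d zero-magnitude pixel(s) set to 0", sum(zero)))
  }
  wrapped_phase_map(ph)
}

# orthonormal DCT-II matrix; t(C) is its inverse
dct_matrix <- function(n) {
  k <- 0:(n - 1L)
  C <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
  C[1L, ] <- C[1L, ] / sqrt(2)
  C
}

dct2 <- function(x, Cr, Cc) Cr %*% x %*% t(Cc)
idct2 <- function(x, Cr, Cc) t(Cr) %*% x %*% Cc

#' Least-squares phase unwrapping via the discrete cosine transform
#'
#' Unweighted least-squares unwrapping: wrapped first differences of the
#' wrapped phase are assembled into a discrete Laplacian, and the Poisson
#' equation is solved under Neumann boundary conditions with the type-II
#' cosine transform. The solution is defined up to an additive constant,
#' fixed here so the minimum over the frame border is 0. Exact (to round-off)
#' whenever the true phase gradient stays below pi per pixel.
#'
#' @param w a [wrapped_phase_map()], both dimensions at least 4.
#' @return a [phase_map()] (pixel size 1 unless set later by the caller).
#' @param pixel_size pixel size (um/px) carried onto the output.
#' @export
unwrap_dct <- function(w, pixel_size = 1) {
  stopifnot(inherits(w, "WrappedPhase"))
  psi <- w$phase
  m <- nrow(psi); n <- ncol(psi)
  if (m < 4L || n < 4L) stop("phase must be at least 4 x 4")

  dx <- wrap_phase(psi[-1L, , drop = FALSE] - psi[-m, , drop = FALSE])
  dy <- wrap_phase(psi[, -1L, drop = FALSE] - psi[, -n, drop = FALSE])
  dxp <- rbind(0, dx); dxp <- rbind(dxp, 0)    # pad: zero flux at borders
  dyp <- cbind(0, dy); dyp <- cbind(dyp, 0)
  rho <- (dxp[-1L, , drop = FALSE] - dxp[-(m + 1L), , drop = FALSE]) +
         (dyp[, -1L, drop = FALSE] - dyp[, -(n + 1L), drop = FALSE])

  Cr <- dct_matrix(m); Cc <- dct_matrix(n)
  rh <- dct2(rho, Cr, Cc)
  denom <- outer(2 * cos(pi * (0:(m - 1L)) / m) - 2,
                 2 * cos(pi * (0:(n - 1L)) / n) - 2, `+`)
  denom[1L, 1L] <- 1
  rh <- rh / denom
  rh[1L, 1L] <- 0
  phi <- idct2(rh, Cr, Cc)

  border <- c(phi[1L, ], phi[m, ], phi[, 1L], phi[, n])
  phase_map(phi - min(border), pixel_size, provenance = "reconstructed")
}

#' Reference the background of a phase map to zero
#'
#' Fits a least-squares plane to background pixels (the complement of
#' `cell_mask`, or the 25% lowest-phase pixels when no mask is supplied),
#' subtracts it, and shifts so the background median is exactly 0.
#'
#' @param p a [phase_map()].
#' @param cell_mask optional logical matrix marking cell pixels; at least 10%
#'   of pixels must remain background.
#' @return a flattened [phase_map()].
#' @export
flatten_background <- function(p, cell_mask = NULL) {
  stopifnot(inherits(p, "PhaseMap"))
  ph <- p$phase
  if (!is.null(cell_mask)) {
    stopifnot(is.logical(cell_mask), identical(dim(cell_mask), dim(ph)))
    bg <- !cell_mask
    if (!any(bg))
      stop("background region is empty; pass a mask leaving background pixels")
    if (mean(bg) < 0.10)
      stop("fewer than 10% background pixels; pass a sparser cell mask")
  } else {
    bg <- ph <= stats::quantile(ph, 0.25, names = FALSE)
  }
  idx <- which(bg, arr.ind = TRUE)
  X <- cbind(1, idx[, 1L], idx[, 2L])
  coef <- stats::lm.fit(X, ph[bg])$coefficients
  plane <- coef[1L] + coef[2L] * row(ph) + coef[3L] * col(ph)
  out <- ph - plane
  out <- out - stats::median(out[bg])
  phase_map(out, p$pixel_size, provenance = p$provenance)
}

#' Full phase reconstruction from an off-axis interferogram
#'
#' Convenience chain: [extract_sideband()] -> [wrapped_phase()] ->
#' [unwrap_dct()] -> [flatten_background()].
#'
#' @param holo an [interferogram()].
#' @param carrier_hint optional carrier (cycles/pixel).
#' @param radius_fraction bandpass radius fraction, in (0, 0.5].
#' @param cell_mask optional logical cell mask for background referencing.
#' @return a flattened [phase_map()].
#' @export
reconstruct_phase <- function(holo, carrier_hint = NULL, radius_fraction = 0.5,
                              cell_mask = NULL) {
  field <- extract_sideband(holo, carrier_hint, radius_fraction)
  w <- wrapped_phase(field)
  p <- unwrap_dct(w, pixel_size = holo$pixel_size)
  flatten_background(p, cell_mask)
}
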