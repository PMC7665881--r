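#' Image containers used throughout the pipeline
#'
#' Images are stored as plain numeric matrices (row = y, column = x, 0-based
#' pixel indices in the maths, 1-based in R subscripts) wrapped in small S3
#' records that carry the optical metadata every downstream stage needs.
#'
#' @name qpi-classes
NULL

#' Construct an off-axis interferogram
#'
#' @param intensity numeric matrix of non-negative camera counts, both
#'   dimensions at least 64 px.
#' @param pixel_size object-space pixel size in micrometres per pixel.
#' @param wavelength illumination wavelength in micrometres (532-nm laser
#'   corresponds to 0.532).
#' @param carrier_hint optional length-2 numeric, the carrier fringe frequency
#'   in cycles per pixel (row, column). `NULL` requests auto-detection.
#' @return an object of class `Interferogram`.
#' @export
interferogram <- function(intensity, pixel_size, wavelength, carrier_hint = NULL) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (!all(is.finite(intensity)) || any(intensity < 0))
    stop("interferogram intensities must be finite and >= 0")
  if (any(dim(intensity) < 64L))
    stop("interferogram must be at least 64 x 64 pixels")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (um/pixel)")
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0)
    stop("wavelength must be a positive scalar (um)")
  if (!is.null(carrier_hint)) {
    stopifnot(is.numeric(carrier_hint), length(carrier_hint) == 2L)
  }
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 wavelength = wavelength, carrier_hint = carrier_hint),
            class = "Interferogram")
}

#' Construct an unwrapped phase map
#'
#' @param phase numeric matrix of unwrapped phase shift in radians.
#' @param pixel_size micrometres per pixel.
#' @param provenance one of `"reconstructed"`, `"synthetic"`, `"loaded"`.
#' @return an object of class `PhaseMap`.
#' @export
phase_map <- function(phase, pixel_size,
                      provenance = c("reconstructed", "synthetic", "loaded")) {
  stopifnot(is.matrix(phase), is.numeric(phase))
  if (!all(is.finite(phase))) stop("phase values must all be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (um/pixel)")
  provenance <- match.arg(provenance)
  structure(list(phase = phase, pixel_size = pixel_size, provenance = provenance),
            class = "PhaseMap")
}

#' Construct a wrapped phase field
#'
#' Values are constrained to the principal branch (-pi, pi].
#'
#' @param phase numeric matrix in radians.
#' @return an object of class `WrappedPhase`.
#' @export
wrapped_phase_map <- function(phase) {
  stopifnot(is.matrix(phase), is.numeric(phase))
  if (!all(is.finite(phase))) stop("wrapped phase must be finite")
  if (any(phase <= -pi) || any(phase > pi))
    stop("wrapped phase must lie in (-pi, pi]")
  structure(list(phase = phase), class = "WrappedPhase")
}

#' Construct an instance label map
#'
#' @param labels integer matrix; 0 = background, 1..N = cell instances.
#'   Labels are renumbered to be consecutive starting at 1.
#' @param pixel_size micrometres per pixel.
#' @return an object of class `LabelMap`.
#' @export
label_map <- function(labels, pixel_size) {
  stopifnot(is.matrix(labels), is.numeric(labels))
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0L)) stop("labels must be non-negative integers")
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (um/pixel)")
  structure(list(labels = labels, pixel_size = pixel_size), class = "LabelMap")
}

#' Number of instances in a label map
#' @param lm a `LabelMap`.
#' @return integer instance count.
#' @export
n_instances <- function(lm) {
  stopifnot(inherits(lm, "LabelMap"))
  as.integer(max(lm$labels))
}

#' Construct a cell thickness map
#'
#' @param thickness numeric matrix in micrometres, 0 outside the cell.
#' @param pixel_size micrometres per pixel.
#' @param mask optional logical support; defaults to `thickness > 0`.
#' @return an object of class `ThicknessMap`.
#' @export
thickness_map <- function(thickness, pixel_size, mask = NULL) {
  stopifnot(is.matrix(thickness), is.numeric(thickness))
  if (!all(is.finite(thickness)) || any(thickness < 0))
    stop("thickness must be finite and non-negative")
  if (is.null(mask)) mask <- thickness > 0
  stopifnot(is.logical(mask), identical(dim(mask), dim(thickness)))
  if (any(thickness[!mask] > 0))
    stop("thickness must be 0 outside the mask support")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (um/pixel)")
  structure(list(thickness = thickness, pixel_size = pixel_size, mask = mask),
            class = "ThicknessMap")
}

#' @export
print.Interferogram <- function(x, ...) {
  cat(sprintf("Interferogram %d x %d px, %.4g um/px, lambda %.4g um\n",
              nrow(x$intensity), ncol(x$intensity), x$pixel_size, x$wavelength))
  invisible(x)
}

#' @export
print.PhaseMap <- function(x, ...) {
  cat(sprintf("PhaseMap %d x %d px, %.4g um/px, range [%.3f, %.3f] rad (%s)\n",
              nrow(x$phase), ncol(x$phase), x$pixel_size,
              min(x$phase), max(x$phase), x$provenance))
  invisible(x)
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("LabelMap %d x %d px, %d instance(s)\n",
              nrow(x$labels), ncol(x$labels), n_instances(x)))
  invisible(x)
}

#' @export
print.ThicknessMap <- function(x, ...) {
  cat(sprintf("ThicknessMap %d x %d px, %.4g um/px, max %.3f um over %d px\n",
              nrow(x$thickness), ncol(x$thickness), x$pixel_size,
              max(x$thickness), sum(x$mask)))
  invisible(x)
}
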