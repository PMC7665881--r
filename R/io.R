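#' TIFF input/output with JSON sidecar metadata
#'
#' Real-valued maps (phase in radians, thickness in micrometres) are written
#' as 32-bit float single-channel TIFFs. Because the TIFF writer stores float
#' samples on a [0, 1] scale, values are affinely rescaled on write and the
#' inverse transform, together with the optical metadata, is recorded in a
#' JSON sidecar `<file>.json`:
#' `value = stored * value_scale + value_offset`.
#' Label maps use 16-bit unsigned TIFF, interferograms 16-bit counts.
#'
#' @name qpi-io
NULL

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

write_float_tiff <- function(x, path, meta = list()) {
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((x - lo) / scale, path, bits.per.sample = 32L, reduce = FALSE)
  meta$value_offset <- lo
  meta$value_scale <- scale
  write_sidecar(path, meta)
  invisible(path)
}

read_float_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1L]
  meta <- read_sidecar(path)
  if (!is.null(meta$value_scale))
    x <- x * meta$value_scale + meta$value_offset
  list(data = x, meta = meta)
}

#' Write / read a phase map as 32-bit float TIFF
#'
#' @param p a [phase_map()].
#' @param path output TIFF path; a `<path>.json` sidecar carries pixel size
#'   and the value scaling.
#' @param wavelength optional wavelength (um) recorded in the sidecar.
#' @return `path`, invisibly (writer); a `PhaseMap` (reader).
#' @export
write_phase_tiff <- function(p, path, wavelength = NULL) {
  stopifnot(inherits(p, "PhaseMap"))
  meta <- list(kind = "phase", units = "radian", pixel_size_um = p$pixel_size,
               provenance = p$provenance)
  if (!is.null(wavelength)) meta$wavelength_um <- wavelength
  write_float_tiff(p$phase, path, meta)
}

#' @rdname write_phase_tiff
#' @param pixel_size fallback pixel size (um/px) when the sidecar is absent.
#' @export
read_phase_tiff <- function(path, pixel_size = NULL) {
  r <- read_float_tiff(path)
  ps <- r$meta$pixel_size_um
  if (is.null(ps)) ps <- pixel_size
  if (is.null(ps)) stop("no pixel size in sidecar; supply `pixel_size`")
  phase_map(r$data, ps, provenance = "loaded")
}

#' Write / read a thickness map as 32-bit float TIFF
#' @param t a [thickness_map()].
#' @param path output path.
#' @return `path` invisibly (writer); a `ThicknessMap` (reader).
#' @export
write_thickness_tiff <- function(t, path) {
  stopifnot(inherits(t, "ThicknessMap"))
  write_float_tiff(t$thickness, path,
                   list(kind = "thickness", units = "um",
                        pixel_size_um = t$pixel_size))
}

#' @rdname write_thickness_tiff
#' @param pixel_size fallback pixel size (um/px) when the sidecar is absent.
#' @export
read_thickness_tiff <- function(path, pixel_size = NULL) {
  r <- read_float_tiff(path)
  ps <- r$meta$pixel_size_um
  if (is.null(ps)) ps <- pixel_size
  if (is.null(ps)) stop("no pixel size in sidecar; supply `pixel_size`")
  x <- pmax(r$data, 0)
  x[x < 1e-9] <- 0  # float round-off from the [0,1] rescaling
  thickness_map(x, ps)
}

#' Write / read an instance label map as 16-bit TIFF
#' @param lm a [label_map()].
#' @param path output path.
#' @return `path` invisibly (writer); a `LabelMap` (reader).
#' @export
write_labels_tiff <- function(lm, path) {
  stopifnot(inherits(lm, "LabelMap"))
  if (max(lm$labels) > 65535L) stop("more than 65535 instances")
  tiff::writeTIFF(lm$labels / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  write_sidecar(path, list(kind = "labels", pixel_size_um = lm$pixel_size))
  invisible(path)
}

#' @rdname write_labels_tiff
#' @param pixel_size fallback pixel size (um/px) when the sidecar is absent.
#' @export
read_labels_tiff <- function(path, pixel_size = NULL) {
  x <- tiff::readTIFF(path)
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1L]
  meta <- read_sidecar(path)
  ps <- meta$pixel_size_um
  if (is.null(ps)) ps <- pixel_size
  if (is.null(ps)) stop("no pixel size in sidecar; supply `pixel_size`")
  label_map(round(x * 65535), ps)
}

#' Write / read an interferogram as 16-bit TIFF counts
#' @param holo an [interferogram()] (counts are rounded to 16-bit).
#' @param path output path.
#' @return `path` invisibly (writer); an `Interferogram` (reader).
#' @export
write_interferogram_tiff <- function(holo, path) {
  stopifnot(inherits(holo, "Interferogram"))
  counts <- pmin(pmax(round(holo$intensity), 0), 65535)
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  write_sidecar(path, list(kind = "interferogram",
                           pixel_size_um = holo$pixel_size,
                           wavelength_um = holo$wavelength,
                           carrier_hint = holo$carrier_hint))
  invisible(path)
}

#' @rdname write_interferogram_tiff
#' @param pixel_size,wavelength fallbacks when the sidecar is absent.
#' @export
read_interferogram_tiff <- function(path, pixel_size = NULL, wavelength = NULL) {
  x <- tiff::readTIFF(path)
  if (is.array(x) && length(dim(x)) == 3L) x <- x[, , 1L]
  meta <- read_sidecar(path)
  ps <- if (!is.null(meta$pixel_size_um)) meta$pixel_size_um else pixel_size
  wl <- if (!is.null(meta$wavelength_um)) meta$wavelength_um else wavelength
  if (is.null(ps) || is.null(wl))
    stop("pixel size and wavelength required (sidecar missing)")
  hint <- meta$carrier_hint
  if (!is.null(hint) && length(hint) != 2L) hint <- NULL
  interferogram(round(x * 65535), ps, wl, carrier_hint = hint)
}
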