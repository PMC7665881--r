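#' Instance segmentation of cells on phase maps
#'
#' A classical marker-controlled watershed segmenter: foreground by Otsu (or
#' fixed) thresholding of the flattened phase, touching cells split by a
#' watershed on the distance transform whose markers are its h-maxima,
#' debris removed by a minimum-area filter. Externally produced masks (for
#' example from a learned segmenter) can be ingested via
#' [read_labels_tiff()] so the downstream feature/classifier path is
#' identical either way.
#'
#' @name segmentation
NULL

#' Segment cells by threshold + marker-controlled watershed
#'
#' @param p a flattened [phase_map()] (background median near 0; a warning is
#'   issued above 0.2 rad).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold phase threshold in radians when `threshold_method` is
#'   `"fixed"`.
#' @param min_area_um2 components smaller than this are discarded
#'   (default 10, well below any red cell's projected area).
#' @param split_touching split touching cells by watershed on the negated
#'   distance transform seeded from its h-maxima.
#' @param h_maxima depth (px) of the h-maxima used as watershed markers.
#' @return a [label_map()]; N = 0 with a warning when no foreground remains.
#' @export
segment_cells <- function(p, threshold_method = c("otsu", "fixed"),
                          threshold = 0.3, min_area_um2 = 10,
                          split_touching = TRUE, h_maxima = 2) {
  stopifnot(inherits(p, "PhaseMap"))
  threshold_method <- match.arg(threshold_method)
  ph <- p$phase
  if (abs(stats::median(ph)) > 0.2)
    warning("phase map does not look background-flattened (|median| > 0.2 rad)")

  if (threshold_method == "otsu") {
    rng <- range(ph)
    if (diff(rng) <= 0) {
      warning("constant phase map; no foreground found")
      return(label_map(matrix(0L, nrow(ph), ncol(ph)), p$pixel_size))
    }
    scaled <- (ph - rng[1L]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * diff(rng) + rng[1L]
  } else {
    thr <- threshold
  }
  fg <- ph > thr
  if (!any(fg)) {
    warning("empty foreground after thresholding")
    return(label_map(matrix(0L, nrow(ph), ncol(ph)), p$pixel_size))
  }
  # biconcave cells can dip below the threshold at the dimple; fill interior
  # holes so each cell is one solid region before splitting
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1))) > 0.5

  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(fg * 1))
    lab <- EBImage::watershed(dm, tolerance = h_maxima, ext = 1)
    labels <- matrix(as.integer(EBImage::imageData(lab)), nrow(ph), ncol(ph))
  } else {
    lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
    labels <- matrix(as.integer(EBImage::imageData(lab)), nrow(ph), ncol(ph))
  }

  min_px <- ceiling(min_area_um2 / p$pixel_size^2)
  tab <- tabulate(labels[labels > 0L])
  drop <- which(tab < min_px)
  if (length(drop)) labels[labels %in% drop] <- 0L
  label_map(labels, p$pixel_size)
}

#' Intersection over union of two boolean masks
#'
#' @param a,b logical matrices of identical shape.
#' @return |a n b| / |a u b|; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b))
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Match predicted to ground-truth instances by IoU
#'
#' Greedy one-to-one matching in descending IoU; candidate pairs below
#' `iou_threshold` are discarded.
#'
#' @param pred,truth [label_map()]s of identical shape.
#' @param iou_threshold minimum IoU for a valid pair.
#' @return an `InstanceMatch` list: `pairs` (data frame pred/truth/iou),
#'   `unmatched_pred`, `unmatched_truth`, `mean_iou` (0 with `no_pairs = TRUE`
#'   when nothing matched).
#' @export
match_instances <- function(pred, truth, iou_threshold = 0.5) {
  stopifnot(inherits(pred, "LabelMap"), inherits(truth, "LabelMap"))
  if (!identical(dim(pred$labels), dim(truth$labels)))
    stop("label map shapes differ")
  np <- n_instances(pred); nt <- n_instances(truth)
  cand <- NULL
  if (np > 0L && nt > 0L) {
    # joint contingency of labels gives all intersections at once
    inter <- table(factor(pred$labels, levels = 0:np),
                   factor(truth$labels, levels = 0:nt))
    ap <- tabulate(pred$labels[pred$labels > 0L], np)
    at <- tabulate(truth$labels[truth$labels > 0L], nt)
    ious <- matrix(0, np, nt)
    for (i in seq_len(np)) for (j in seq_len(nt)) {
      int <- inter[i + 1L, j + 1L]
      if (int > 0) ious[i, j] <- int / (ap[i] + at[j] - int)
    }
    ord <- order(ious, decreasing = TRUE)
    used_p <- logical(np); used_t <- logical(nt)
    rows <- list()
    for (o in ord) {
      v <- ious[o]
      if (v < iou_threshold || v <= 0) break
      i <- (o - 1L) %% np + 1L
      j <- (o - 1L) %/% np + 1L
      if (used_p[i] || used_t[j]) next
      used_p[i] <- TRUE; used_t[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(pred = i, truth = j, iou = v)
    }
    cand <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  if (is.null(cand))
    cand <- data.frame(pred = integer(), truth = integer(), iou = numeric())
  structure(list(
    pairs = cand,
    unmatched_pred = setdiff(seq_len(np), cand$pred),
    unmatched_truth = setdiff(seq_len(nt), cand$truth),
    mean_iou = if (nrow(cand)) mean(cand$iou) else 0,
    no_pairs = nrow(cand) == 0L
  ), class = "InstanceMatch")
}

# inverse-map rotation about the image centre; bilinear or nearest lookup
rotate_grid <- function(img, angle_deg, bilinear = TRUE) {
  m <- nrow(img); n <- ncol(img)
  cy <- (m + 1) / 2; cx <- (n + 1) / 2
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  r <- row(img) - cy; c <- col(img) - cx
  # source coordinates (rotate backwards)
  sr <- co * r + si * c + cy
  sc <- -si * r + co * c + cx
  if (bilinear) {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gv <- function(ri, ci) {
      ok <- ri >= 1 & ri <= m & ci >= 1 & ci <= n
      out <- numeric(length(ri))
      out[ok] <- img[cbind(ri[ok], ci[ok])]
      out
    }
    v <- (1 - fr) * (1 - fc) * gv(r0, c0) + (1 - fr) * fc * gv(r0, c0 + 1) +
         fr * (1 - fc) * gv(r0 + 1, c0) + fr * fc * gv(r0 + 1, c0 + 1)
    matrix(v, m, n)
  } else {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= m & ci >= 1 & ci <= n
    out <- numeric(length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    matrix(out, m, n)
  }
}

#' Rotate an image and its mask about the image centre
#'
#' The image is interpolated bilinearly, the mask by nearest neighbour and
#' re-binarized; out-of-frame regions fill with 0. Angles that are multiples
#' of 90 degrees on square grids reduce to exact pixel permutations.
#'
#' @param image numeric matrix.
#' @param mask logical matrix, same shape.
#' @param angle_deg rotation angle in `[0, 360)`.
#' @param rng_seed unused for a fixed angle; kept so augmentation pipelines
#'   can thread a seed through.
#' @return list with `image` and `mask`.
#' @export
augment_rotate <- function(image, mask, angle_deg, rng_seed = NULL) {
  stopifnot(is.matrix(image), is.logical(mask),
            identical(dim(image), dim(mask)))
  if (angle_deg < 0 || angle_deg >= 360) stop("angle must be in [0, 360)")
  if (any(mask[1L, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1L]) || any(mask[, ncol(mask)]))
    warning("mask touches the frame border; rotation may lose content")
  if (angle_deg == 0) return(list(image = image, mask = mask))
  if (angle_deg %% 90 == 0 && nrow(image) == ncol(image)) {
    k <- (angle_deg / 90) %% 4
    # one 90-degree permutation applied k times
    rot1 <- function(x) t(x[rev(seq_len(nrow(x))), , drop = FALSE])
    im <- image; mk <- mask
    for (i in seq_len(k)) { im <- rot1(im); mk <- rot1(mk) }
    return(list(image = im, mask = mk))
  }
  list(image = rotate_grid(image, angle_deg, bilinear = TRUE),
       mask = rotate_grid(mask * 1, angle_deg, bilinear = FALSE) > 0.5)
}
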