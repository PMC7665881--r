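#' End-to-end pipeline orchestration
#'
#' Reproducible desk-scale runs over synthetic populations: phantom
#' generation, optional hologram round trip, segmentation, 2-D and 3-D
#' feature extraction, grouped split + gradient-boosted classification,
#' exact Shapley attribution, and CCA of phase statistics against 3-D
#' morphology. Every stage writes its artifact plus a JSON manifest with the
#' resolved configuration and seeds, so a run re-executed from its saved
#' config reproduces all outputs.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @return nested list of stage parameters and seeds; serializable to YAML.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    pixel_size_um = 0.08,
    wavelength_um = 0.532,
    population = list(n_per_class = 200L),
    segmentation = list(method = "otsu", min_area_um2 = 10, h_maxima = 2,
                        mode = "watershed"),   # or "truth"
    features = list(glcm_levels = 32L, glcm_distance = 1L),
    thickness = list(delta_n = 0.06),
    classifier = list(split = c(0.8, 0.2), max_depth = 3L, nrounds = 200L,
                      eta = 0.1),
    shapley = list(n_instances = 12L, n_background = 20L),
    scene_eval = list(n_scenes = 3L, cells_per_scene = 5L, shape = c(400L, 400L),
                      min_gap_px = 6L),
    version = as.character(utils::packageVersion("qpirbc"))
  )
}

# per-cell mask: ground truth support, or watershed on the rendered phase
cell_mask_for <- function(rendered, mode, seg_cfg) {
  if (mode == "truth") return(rendered$mask)
  lm <- segment_cells(rendered$phase, threshold_method = seg_cfg$method,
                      min_area_um2 = seg_cfg$min_area_um2,
                      h_maxima = seg_cfg$h_maxima)
  if (n_instances(lm) == 0L) return(rendered$mask)
  sizes <- tabulate(lm$labels[lm$labels > 0L])
  lm$labels == which.max(sizes)
}

#' Build the per-cell feature table for a phantom population
#'
#' Renders each phantom on its own canvas, derives the cell mask (ground
#' truth or watershed segmentation of the phase map), and extracts the 15
#' 2-D features plus the six 3-D features, together with the analytic ground
#' truth. By default the 3-D features are computed from the generator's
#' clean thickness map, emulating a second, independent 3-D measurement of
#' the same cell (as a tomographic modality would provide); with
#' `three_d = "phase"` they are instead derived from the same noisy phase
#' map via the constant-RI inversion [thickness_from_phase()].
#'
#' @param specs list of [phantom_spec()] from [sample_population()].
#' @param pixel_size micrometres per pixel.
#' @param segment `"truth"` or `"watershed"`.
#' @param glcm_levels,glcm_distance texture parameters.
#' @param delta_n refractive-index contrast for the phase-to-thickness
#'   inversion; `NULL` uses each phantom's own contrast.
#' @param phase_noise_sd,texture_sd per-cell realism perturbations passed to
#'   [render_phantom()] (defaults emulate single-shot reconstruction noise
#'   and mild hemoglobin inhomogeneity).
#' @param rng_seed base seed for the per-cell perturbations.
#' @param three_d `"tomogram"` (3-D features from the clean generator
#'   thickness, an independent-modality analogue) or `"phase"` (from the
#'   noisy phase via the constant-RI inversion).
#' @return data frame: `cell_id`, `class`, 15 2-D features, 7 3-D columns,
#'   and truth columns `true_volume_um3`, `true_ov_rad_um2`, `true_t_0_um`,
#'   `true_delta_75_um`.
#' @export
population_feature_table <- function(specs, pixel_size = 0.08,
                                     segment = c("truth", "watershed"),
                                     glcm_levels = 32L, glcm_distance = 1L,
                                     delta_n = NULL, phase_noise_sd = 0.08,
                                     texture_sd = 0.05, rng_seed = 1L,
                                     three_d = c("tomogram", "phase")) {
  three_d <- match.arg(three_d)
  segment <- match.arg(segment)
  seg_cfg <- list(method = "otsu", min_area_um2 = 10, h_maxima = 2)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    r <- render_phantom(sp, pixel_size = pixel_size,
                        phase_noise_sd = phase_noise_sd,
                        texture_sd = texture_sd,
                        rng_seed = (rng_seed + i * 7919) %% 2147483647)
    mask <- cell_mask_for(r, segment, seg_cfg)
    lm <- label_map(mask * 1L, pixel_size)
    f2 <- extract_features(r$phase, lm, class = sp$cell_class,
                           glcm_levels = glcm_levels,
                           glcm_distance = glcm_distance)
    if (!nrow(f2)) next
    if (three_d == "tomogram") {
      tm <- r$thickness
      lm <- label_map(r$mask * 1L, pixel_size)  # tomogram has its own support
    } else {
      dn <- if (is.null(delta_n)) sp$delta_n else delta_n
      tm <- thickness_from_phase(r$phase, mask, delta_n = dn,
                                 wavelength = sp$wavelength)
    }
    f3 <- extract_features_3d(tm, lm)
    tr <- r$truth
    row <- cbind(f2[1L, ], f3[1L, -1L],
                 data.frame(true_volume_um3 = tr$volume_um3,
                            true_ov_rad_um2 = tr$ov_rad_um2,
                            true_t_0_um = tr$t_0_um,
                            true_delta_75_um = tr$delta_75_um))
    row$cell_id <- i
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Evaluate watershed segmentation on composed scenes
#'
#' @param specs list of phantoms to place per scene (recycled).
#' @param n_scenes number of scenes.
#' @param cells_per_scene phantoms per scene.
#' @param shape,pixel_size,min_gap_px canvas geometry.
#' @param seed placement seed (one offset per scene).
#' @return list with `mean_iou` over all matched cells, `n_matched`,
#'   `n_truth`, and the per-scene [match_instances()] results.
#' @export
evaluate_segmentation <- function(specs, n_scenes = 3L, cells_per_scene = 5L,
                                  shape = c(400L, 400L), pixel_size = 0.08,
                                  min_gap_px = 6L, seed = 1L) {
  ious <- numeric(); matches <- list(); n_truth <- 0L
  for (s in seq_len(n_scenes)) {
    take <- ((s - 1L) * cells_per_scene + seq_len(cells_per_scene) - 1L) %%
      length(specs) + 1L
    scene <- compose_scene(specs[take], shape = shape, pixel_size = pixel_size,
                           min_gap_px = min_gap_px, rng_seed = seed + s)
    pred <- segment_cells(scene$phase)
    mi <- match_instances(pred, scene$labels)
    ious <- c(ious, mi$pairs$iou)
    n_truth <- n_truth + n_instances(scene$labels)
    matches[[s]] <- mi
  }
  list(mean_iou = if (length(ious)) mean(ious) else 0,
       n_matched = length(ious), n_truth = n_truth, matches = matches)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate -> features (2-D + 3-D) -> split/train/evaluate ->
#' Shapley attribution -> CCA -> scene segmentation evaluation, writing
#' `features.csv`, `metrics.json`, `importance.csv`, `cca.json`,
#' `segmentation.json`, the trained model, and `manifest.json` (resolved
#' config, seeds, per-stage counts) into `out_dir`.
#'
#' @param config list as from [default_config()] (missing fields filled with
#'   defaults).
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("qpirun")) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$wavelength_um) || !is.numeric(cfg$wavelength_um))
    stop("config field wavelength_um is missing or not numeric")
  if (is.null(cfg$pixel_size_um) || !is.numeric(cfg$pixel_size_um))
    stop("config field pixel_size_um is missing or not numeric")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  specs <- sample_population(cfg$population$n_per_class,
                             rng_seed = cfg$seed,
                             wavelength = cfg$wavelength_um)
  counts$n_cells <- length(specs)

  feats <- population_feature_table(
    specs, pixel_size = cfg$pixel_size_um,
    segment = if (identical(cfg$segmentation$mode, "truth")) "truth" else "watershed",
    glcm_levels = cfg$features$glcm_levels,
    glcm_distance = cfg$features$glcm_distance)
  utils::write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  counts$n_feature_rows <- nrow(feats)

  parts <- split_dataset(feats, ratios = cfg$classifier$split,
                         group_col = "cell_id", seed = cfg$seed + 1L)
  model <- train_classifier(parts$train, max_depth = cfg$classifier$max_depth,
                            nrounds = cfg$classifier$nrounds,
                            eta = cfg$classifier$eta, seed = cfg$seed + 2L)
  metrics <- evaluate(model, parts$test)
  save_classifier(model, file.path(out_dir, "model"))
  jsonlite::write_json(
    list(sensitivity = metrics$sensitivity, specificity = metrics$specificity,
         accuracy = metrics$accuracy, f1 = metrics$f1, auc = metrics$auc,
         confusion = as.list(metrics$confusion)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)

  nb <- min(cfg$shapley$n_background, nrow(parts$train))
  ni <- min(cfg$shapley$n_instances, nrow(parts$test))
  bg <- parts$train[with_seed(cfg$seed + 3L, sample(nrow(parts$train), nb)),
                    model$features, drop = FALSE]
  inst <- parts$test[with_seed(cfg$seed + 4L, sample(nrow(parts$test), ni)),
                     model$features, drop = FALSE]
  shap <- shapley_exact(classifier_margin_fn(model), inst, bg)
  utils::write.csv(global_importance(shap),
                   file.path(out_dir, "importance.csv"), row.names = FALSE)

  xcols <- c("ov_rad_um2", "phase_mean_rad", "phase_p5_rad", "phase_sd_rad")
  ycols <- c("volume_um3", "sv_ratio_per_um", "sphericity", "t_avg_um",
             "t_0_um", "delta_75_um")
  cca <- cca_fit(feats[, xcols], feats[, ycols])
  jsonlite::write_json(
    list(correlations = cca$correlations,
         shared_variance = cca$shared_variance,
         loadings_x = as.data.frame(cca$loadings_x),
         loadings_y = as.data.frame(cca$loadings_y)),
    file.path(out_dir, "cca.json"), digits = NA)

  seg <- evaluate_segmentation(specs,
                               n_scenes = cfg$scene_eval$n_scenes,
                               cells_per_scene = cfg$scene_eval$cells_per_scene,
                               shape = cfg$scene_eval$shape,
                               pixel_size = cfg$pixel_size_um,
                               min_gap_px = cfg$scene_eval$min_gap_px,
                               seed = cfg$seed + 5L)
  jsonlite::write_json(list(mean_iou = seg$mean_iou, n_matched = seg$n_matched,
                            n_truth = seg$n_truth),
                       file.path(out_dir, "segmentation.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(config = cfg, counts = counts,
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  invisible(list(config = cfg, features = feats, model = model,
                 metrics = metrics, shapley = shap, cca = cca,
                 segmentation = seg, out_dir = out_dir))
}
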