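# End-to-end orchestration of the four-step pipeline:
# (1) contrast stretch + color model, (2) unstained-cell removal,
# (3) probabilistic four-phase level set + component filtering,
# (4) cluster splitting (watershed + circular Hough + area-ratio filter).

#' Pipeline configuration
#'
#' Collects every tunable of the four steps. Unknown keys are rejected and
#' ranges validated.
#'
#' @param variant `"tool1"` (k-means nuclei mask for cluster splitting,
#'   the recommended default) or `"tool2"` (nucleus-phase mask).
#' @param sat_frac contrast-stretch saturated fraction per tail.
#' @param hue_threshold unstained-cell hue cutoff on the 8-bit scale.
#' @param background_source `"model"` (background-region color means) or
#'   `"border"` (median of the image border strip).
#' @param t_pc,t_bg weight-rule thresholds for plasma-cell regions and for
#'   background/unstained regions.
#' @param levelset a [level_set_params()] list.
#' @param init_radius,init_spacing level-set seeding circle grid, pixels, at
#'   the reference working size (`ref_size`); scaled proportionally for
#'   smaller images.
#' @param ref_size image side at which `init_radius`/`init_spacing` apply.
#' @param min_component_px minimum stained-component size kept after the
#'   level set.
#' @param min_cytoplasm_frac minimum cytoplasm area of a kept component,
#'   as a fraction of the median component area.
#' @param kmeans_seed seed for the k-means nuclei mask.
#' @param nuclei_opening_px diameter (pixels, odd) of the disc used to
#'   morphologically open the nuclei mask before cluster splitting,
#'   suppressing pixel speckle; 0 disables.
#' @param cht_sensitivity circular-Hough peak threshold.
#' @param cht_range optional fixed `c(r_min, r_max)`; `NULL` = derive from
#'   the stained components ([default_cht_range()]).
#' @param ratio_max nucleus-to-cell area-ratio cutoff.
#' @param iou_complete IoU threshold used when evaluating detections.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(variant = c("tool1", "tool2"),
                            sat_frac = 0.01,
                            hue_threshold = 120,
                            background_source = c("model", "border"),
                            t_pc = 1, t_bg = 3,
                            levelset = level_set_params(),
                            init_radius = 8, init_spacing = 24,
                            ref_size = 1920,
                            min_component_px = 200,
                            min_cytoplasm_frac = 0.1,
                            kmeans_seed = 1,
                            nuclei_opening_px = 5,
                            cht_sensitivity = 0.25,
                            cht_range = NULL,
                            ratio_max = 0.85,
                            iou_complete = 0.7) {
  variant <- match.arg(variant)
  background_source <- match.arg(background_source)
  stopifnot(sat_frac >= 0, sat_frac < 0.5,
            hue_threshold >= 0, hue_threshold <= 255,
            inherits(levelset, "level_set_params"),
            min_component_px >= 0, min_cytoplasm_frac >= 0,
            cht_sensitivity > 0, ratio_max > 0, ratio_max <= 1,
            iou_complete > 0, iou_complete <= 1)
  structure(list(variant = variant, sat_frac = sat_frac,
                 hue_threshold = hue_threshold,
                 background_source = background_source,
                 t_pc = t_pc, t_bg = t_bg, levelset = levelset,
                 init_radius = init_radius, init_spacing = init_spacing,
                 ref_size = ref_size,
                 min_component_px = min_component_px,
                 min_cytoplasm_frac = min_cytoplasm_frac,
                 kmeans_seed = kmeans_seed,
                 nuclei_opening_px = nuclei_opening_px,
                 cht_sensitivity = cht_sensitivity, cht_range = cht_range,
                 ratio_max = ratio_max, iou_complete = iou_complete),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; a nested `levelset`
#' block maps to [level_set_params()]. Unknown keys abort.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ls_args <- raw$levelset
  raw$levelset <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(ls_args)) {
    bad <- setdiff(names(ls_args), names(formals(level_set_params)))
    if (length(bad))
      stop("unknown levelset key(s): ", paste(bad, collapse = ", "))
    raw$levelset <- do.call(level_set_params, ls_args)
  }
  if (!is.null(raw$cht_range)) raw$cht_range <- as.numeric(raw$cht_range)
  do.call(pipeline_config, raw)
}

#' Run the full segmentation pipeline on one image
#'
#' Steps: percentile contrast stretch; nine-channel expansion; hue-threshold
#' replacement of unstained cells by the background color; per-region
#' probability maps and distance images under the fitted color model with
#' Bhattacharyya-derived channel weights; four-phase level-set evolution;
#' small-component and scant-cytoplasm filtering of the stained mask; then
#' cluster splitting with the variant's nuclei mask (k-means for tool1, the
#' nucleus phase for tool2), nucleus-seeded watershed, a circular-Hough
#' circularity gate and the nucleus/cell area-ratio filter.
#'
#' @param img `H x W x 3` 8-bit RGB array (or a file path readable by
#'   [read_rgb_image()]).
#' @param model fitted `region_color_model` (means/sds per region and
#'   channel). Required: the method is color-model driven.
#' @param config a [pipeline_config()].
#' @param distances optional 9 x 6 distance table to derive the channel
#'   weights from; default is the closed-form table of `model`. Supply
#'   [reference_distance_table()] to use the published weights.
#' @return list of class `pipeline_result`: `cells` (a `cell_instance_set`
#'   after all filters), `phase_mask`, `stained`, `nuclei_mask`,
#'   `energy_log`, `weights`, and the intermediate images.
#' @export
run_pipeline <- function(img, model, config = pipeline_config(),
                         distances = NULL) {
  if (is.character(img)) img <- read_rgb_image(img)
  u0 <- contrast_stretch(img, config$sat_frac)
  stack0 <- to_channel_stack(u0)
  bg <- switch(config$background_source,
               model = model$mean["background", c("R", "G", "B")],
               border = border_median_color(u0))
  cleaned <- remove_unstained(stack0, u0, config$hue_threshold, bg_color = bg)
  stack <- to_channel_stack(cleaned)

  if (is.null(distances)) distances <- distance_table(model)
  weights <- assign_weights(distances, t_pc = config$t_pc, t_bg = config$t_bg)
  pmaps <- probability_maps(stack, model, weights)
  dimgs <- distance_images(stack, model, weights)

  scale <- min(1, min(dim(u0)[1:2]) / config$ref_size)
  state <- init_phis(dim(u0)[1:2],
                     radius = max(3, round(config$init_radius * scale)),
                     spacing = max(8, round(config$init_spacing * scale)))
  state <- evolve(state, pmaps, dimgs, config$levelset)
  phase <- extract_phase_mask(state)
  stained0 <- stained_mask(phase)

  nuclei_src <- switch(config$variant,
                       tool1 = nuclei_mask_kmeans(stack, stained0,
                                                  seed = config$kmeans_seed),
                       tool2 = nuclei_mask_levelset(phase))
  labs0 <- as.matrix(EBImage::bwlabel(matrix(as.numeric(stained0),
                                             nrow(stained0))))
  med_area <- if (max(labs0) > 0)
    stats::median(tabulate(labs0[labs0 > 0], nbins = max(labs0))) else 0
  stained <- postfilter_components(
    stained0, nuclei_src,
    min_component_px = config$min_component_px,
    min_cytoplasm_px = config$min_cytoplasm_frac * med_area)
  nuclei <- nuclei_src & stained
  if (config$nuclei_opening_px >= 3) {
    brush <- EBImage::makeBrush(config$nuclei_opening_px, "disc")
    nuclei <- as.matrix(EBImage::opening(
      matrix(as.numeric(nuclei), nrow(nuclei)), brush)) > 0
  }

  rng <- config$cht_range
  if (is.null(rng)) rng <- default_cht_range(stained)
  nuc_labels <- split_nuclei(nuclei, sensitivity = config$cht_sensitivity)
  cells <- split_cells(stained, nuc_labels, r_min = rng[1], r_max = rng[2],
                       sensitivity = config$cht_sensitivity)
  cells <- filter_by_nucleus_ratio(cells, config$ratio_max)

  structure(list(cells = cells, phase_mask = phase, stained = stained,
                 nuclei_mask = nuclei, nuclei_labels = nuc_labels,
                 energy_log = attr(state, "energy_log"),
                 weights = weights, contrast_stretched = u0,
                 cleaned = cleaned),
            class = "pipeline_result")
}

#' Evaluate predictions against ground truth, pooled over images
#'
#' Matches each prediction to its truth at `config$iou_complete`, pools the
#' counts (micro-averaging) and computes the metrics once on the totals.
#'
#' @param preds list of predicted label matrices or `cell_instance_set`s.
#' @param truths list of ground-truth instance label matrices.
#' @param config a [pipeline_config()] (for the IoU threshold).
#' @return list with `counts` (pooled `detection_counts`) and `report`
#'   (`metric_report`).
#' @export
evaluate_detections <- function(preds, truths, config = pipeline_config()) {
  stopifnot(length(preds) == length(truths))
  counts <- mapply(function(p, t) match_instances(p, t, config$iou_complete),
                   preds, truths, SIMPLIFY = FALSE)
  pooled <- pool_counts(counts)
  list(counts = pooled, report = compute_metrics(pooled))
}

#' Read / write 8-bit RGB images
#'
#' Thin wrappers over EBImage I/O (PNG/TIFF/BMP/JPEG) converting between
#' EBImage's `[0, 1]` x-major layout and this package's `H x W x 3` arrays
#' on `[0, 255]`.
#'
#' @param path image file.
#' @return `read_rgb_image`: numeric `H x W x 3` array in `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  im <- EBImage::readImage(path)
  d <- dim(im)
  if (length(d) == 2L) {
    arr <- array(rep(t(as.matrix(im)), 3L), c(d[2], d[1], 3L))
  } else {
    arr <- aperm(im@.Data[, , 1:3], c(2, 1, 3))
  }
  round(arr * 255)
}

#' @rdname read_rgb_image
#' @param img `H x W x 3` array in `[0, 255]`.
#' @export
write_rgb_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(aperm(img / 255, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write a label matrix as a 16-bit TIFF
#'
#' @param labels integer matrix.
#' @param path output TIFF path.
#' @export
write_label_tiff <- function(labels, path) {
  EBImage::writeImage(EBImage::Image(t(labels) / 65535), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Write the per-instance table of a `cell_instance_set` as CSV
#'
#' Columns: label, area, nucleus_area, ratio, centroid_row, centroid_col,
#' circular; coordinates are 0-based (row, col).
#'
#' @param cells a `cell_instance_set`.
#' @param path output CSV path.
#' @export
write_instance_csv <- function(cells, path) {
  df <- cells$instances
  df$centroid_row <- df$centroid_row - 1
  df$centroid_col <- df$centroid_col - 1
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
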