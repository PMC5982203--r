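#' Pipeline configuration
#'
#' One configuration object ties the stages together (mask generation,
#' training, detection, evaluation, survey). Defaults reproduce the reference
#' settings: 20-px marks, penalty weights {0, 50, 75}, softmax thresholds
#' 0.1-0.9, matching tolerance one mark diameter, and the 40-epoch Adagrad
#' schedule with rate drops after epochs 32 and 36. Values can come from a
#' YAML file with overrides on top.
#'
#' @param ... field overrides (see Details).
#' @param yaml_path optional YAML file whose entries are applied before
#'   `...`.
#' @details Fields: `out_dir`, `images_dir`, `annotations_csv`,
#'   `mark_diameter`, `halo_radius`, `penalty_weights`, `softmax_thresholds`,
#'   `tolerance`, `min_area`, `epochs`, `initial_lr`, `lr_drop_epochs`,
#'   `lr_drop_factor`, `crop_size`, `backbone`, `scene_specs` (synthetic
#'   mode), `seed`.
#' @return Object of class `psep_config` (a named list).
#' @export
pipeline_config <- function(..., yaml_path = NULL) {
  cfg <- list(
    out_dir = ".", images_dir = NULL, annotations_csv = NULL,
    mark_diameter = 20, halo_radius = 10,
    penalty_weights = c(0, 50, 75),
    softmax_thresholds = seq(0.1, 0.9, by = 0.1),
    tolerance = 20, min_area = 1,
    epochs = 40, initial_lr = 1e-3, lr_drop_epochs = c(32, 36),
    lr_drop_factor = 2, crop_size = 1500,
    retrain_epochs = NULL, retrain_lr = NULL, retrain_lr_drop_epochs = NULL,
    backbone = "mini", scene_specs = NULL, seed = 1)
  if (!is.null(yaml_path))
    cfg <- utils::modifyList(cfg, yaml::read_yaml(yaml_path))
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "psep_config"
  cfg
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  # small stable checksum, enough to recognize a config in logs
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(s))) %% 1e9
}

log_stage <- function(cfg, stage, verbose = TRUE) {
  if (verbose)
    message(sprintf("[psep] %s  seed=%d  config#%d", stage, cfg$seed,
                    config_hash(cfg)))
}

require_artifact <- function(path, hint) {
  if (!file.exists(path))
    stopf("missing upstream artifact: %s (run `%s` first)", path, hint)
  path
}

schedule_from_config <- function(cfg, images = NULL) {
  crop <- cfg$crop_size
  if (!is.null(crop) && !is.null(images)) {
    sides <- vapply(images, function(x) min(dim(x)[1:2]), numeric(1))
    if (crop > min(sides)) crop <- NULL  # images smaller than the crop: use full frames
  }
  training_schedule(epochs = cfg$epochs, initial_lr = cfg$initial_lr,
                    lr_drop_epochs = cfg$lr_drop_epochs,
                    lr_drop_factor = cfg$lr_drop_factor,
                    crop_size = crop, seed = cfg$seed)
}

#' Pipeline stage: generate synthetic scenes
#'
#' Renders the configured `scene_specs` into `<out_dir>/scenes` (PNGs plus an
#' annotation CSV).
#'
#' @param cfg a [pipeline_config()] with non-NULL `scene_specs`.
#' @param verbose log a stage line to stderr.
#' @return The scene list, invisibly.
#' @export
cmd_synth <- function(cfg, verbose = TRUE) {
  log_stage(cfg, "synth", verbose)
  if (is.null(cfg$scene_specs)) stopf("`scene_specs` not set in config")
  dir <- file.path(cfg$out_dir, "scenes")
  scenes <- generate_dataset(cfg$scene_specs, dir = dir)
  invisible(scenes)
}

#' Pipeline stage: rasterize annotations into mask files
#'
#' Reads the annotation CSV, rasterizes a label mask per annotated image and
#' writes encoded mask PNGs plus a manifest CSV. Images present on disk but
#' missing from the CSV are listed in the manifest as skipped.
#'
#' @param cfg a [pipeline_config()] with `images_dir` and `annotations_csv`.
#' @param verbose log a stage line to stderr.
#' @return data.frame manifest (`image_id`, `mask_path`, `status`),
#'   invisibly.
#' @export
cmd_make_masks <- function(cfg, verbose = TRUE) {
  log_stage(cfg, "make-masks", verbose)
  imgs <- list.files(cfg$images_dir %||% ".", pattern = "\\.png$",
                     full.names = TRUE)
  imgs <- imgs[basename(imgs) != "annotations.csv"]
  mask_dir <- file.path(cfg$out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
  ann_df <- if (!is.null(cfg$annotations_csv) &&
                file.exists(cfg$annotations_csv))
    utils::read.csv(cfg$annotations_csv) else
      data.frame(image_id = character(0), row = numeric(0), col = numeric(0))
  rows <- list()
  for (path in imgs) {
    id <- sub("\\.png$", "", basename(path))
    img <- png::readPNG(path)
    sub <- ann_df[as.character(ann_df$image_id) == id, , drop = FALSE]
    if (nrow(sub) == 0 && !(id %in% ann_df$image_id)) {
      rows[[id]] <- data.frame(image_id = id, mask_path = NA_character_,
                               status = "skipped: no annotation")
      next
    }
    ann <- point_annotation(cbind(sub$row, sub$col), dim(img)[1:2],
                            mark_diameter = cfg$mark_diameter)
    lab <- rasterize_marks(ann)
    halo <- halo_mask(ann, cfg$halo_radius)
    mp <- file.path(mask_dir, paste0(id, "_mask.png"))
    write_mask_png(lab, mp, halo = halo, debug = TRUE)
    rows[[id]] <- data.frame(image_id = id, mask_path = mp, status = "ok")
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), mask_path = character(0),
               status = character(0))
  utils::write.csv(manifest, file.path(mask_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# load scenes written by cmd_synth back as training material
load_scene_dir <- function(dir) {
  ann_csv <- require_artifact(file.path(dir, "annotations.csv"), "synth")
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  scenes <- list()
  shapes <- list()
  imgs <- list()
  for (p in paths) {
    id <- sub("\\.png$", "", basename(p))
    imgs[[id]] <- png::readPNG(p)
    shapes[[id]] <- dim(imgs[[id]])[1:2]
  }
  anns <- read_annotations_csv(ann_csv, shapes)
  for (id in names(imgs))
    scenes[[id]] <- list(image = imgs[[id]], annotation = anns[[id]])
  scenes
}

#' Pipeline stage: train a model per penalty weight
#'
#' Trains a weight-0 baseline first, derives penalty regions from its false
#' positives on the training scenes, then (re)trains one model per positive
#' penalty weight with those regions in the weight masks. Checkpoints and
#' loss logs go under `<out_dir>/models`.
#'
#' @param cfg a [pipeline_config()]; scenes are read from
#'   `<out_dir>/scenes`.
#' @param verbose log stage lines to stderr.
#' @return Named list of trained models (one per penalty weight), invisibly.
#' @export
cmd_train <- function(cfg, verbose = TRUE) {
  log_stage(cfg, "train", verbose)
  scenes <- load_scene_dir(file.path(cfg$out_dir, "scenes"))
  for (id in names(scenes))
    scenes[[id]]$annotation$mark_diameter <- cfg$mark_diameter
  model_dir <- file.path(cfg$out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE, recursive = TRUE)
  images <- lapply(scenes, `[[`, "image")
  sch <- schedule_from_config(cfg, images)
  retrain <- training_schedule(
    epochs = cfg$retrain_epochs %||% sch$epochs,
    initial_lr = cfg$retrain_lr %||% (sch$initial_lr / 5),
    lr_drop_epochs = cfg$retrain_lr_drop_epochs %||% sch$lr_drop_epochs,
    lr_drop_factor = sch$lr_drop_factor, crop_size = sch$crop_size,
    seed = cfg$seed + 1L)
  grid <- train_penalty_grid(
    scenes, weights = cfg$penalty_weights, spec = fcn_spec(cfg$backbone),
    base_schedule = sch, retrain_schedule = retrain,
    halo_radius = cfg$halo_radius, exclusion_radius = cfg$mark_diameter,
    verbose = verbose)
  fcn_save(grid$primary, file.path(model_dir, "model_primary.rds"),
           schedule = sch)
  write_loss_log(grid$logs$primary, file.path(model_dir, "loss_primary.csv"))
  for (key in names(grid$models)) {
    fcn_save(grid$models[[key]],
             file.path(model_dir, paste0("model_p", key, ".rds")),
             schedule = retrain)
    write_loss_log(grid$logs[[key]],
                   file.path(model_dir, paste0("loss_p", key, ".csv")))
  }
  invisible(grid$models)
}

#' Pipeline stage: detect points
#'
#' Runs a trained checkpoint over the scene images and writes a detections
#' CSV (plus per-image PSEP probability maps as PNGs) under
#' `<out_dir>/detections`.
#'
#' @param cfg a [pipeline_config()].
#' @param penalty_weight which trained checkpoint to use (default: largest
#'   configured weight).
#' @param threshold softmax threshold (default 0.4, the reference operating
#'   point).
#' @param verbose log a stage line to stderr.
#' @return Named list of detections, invisibly.
#' @export
cmd_detect <- function(cfg, penalty_weight = max(cfg$penalty_weights),
                       threshold = 0.4, verbose = TRUE) {
  log_stage(cfg, "detect", verbose)
  scenes <- load_scene_dir(file.path(cfg$out_dir, "scenes"))
  ckpt <- require_artifact(
    file.path(cfg$out_dir, "models", paste0("model_p", penalty_weight, ".rds")),
    "train")
  model <- fcn_load(ckpt)
  det_dir <- file.path(cfg$out_dir, "detections")
  dir.create(det_dir, showWarnings = FALSE, recursive = TRUE)
  dets <- list()
  for (id in names(scenes)) {
    probs <- fcn_predict(model, scenes[[id]]$image)
    png::writePNG(probs[, , 2], file.path(det_dir, paste0(id, "_prob.png")))
    dets[[id]] <- extract_points(threshold_softmax(probs, threshold),
                                 min_area = cfg$min_area)
  }
  write_detections_csv(dets, file.path(det_dir, "detections.csv"))
  invisible(dets)
}

#' Pipeline stage: evaluate the model grid
#'
#' Sweeps the configured penalty weights (using the checkpoints from
#' [cmd_train()]) against all softmax thresholds on the scenes, writing the
#' grid CSV and per-image match visualizations at the best cell.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log a stage line to stderr.
#' @return The [grid_evaluate()] result, invisibly.
#' @export
cmd_eval <- function(cfg, verbose = TRUE) {
  log_stage(cfg, "eval", verbose)
  scenes <- load_scene_dir(file.path(cfg$out_dir, "scenes"))
  for (id in names(scenes))
    scenes[[id]]$annotation$mark_diameter <- cfg$mark_diameter
  model_dir <- file.path(cfg$out_dir, "models")
  eval_dir <- file.path(cfg$out_dir, "evaluation")
  dir.create(eval_dir, showWarnings = FALSE, recursive = TRUE)
  loaders <- function(wt) {
    fcn_load(require_artifact(
      file.path(model_dir, paste0("model_p", wt, ".rds")), "train"))
  }
  grid <- grid_evaluate(loaders, scenes, weights = cfg$penalty_weights,
                        thresholds = cfg$softmax_thresholds,
                        tolerance = cfg$tolerance, min_area = cfg$min_area)
  write_grid_csv(grid, file.path(eval_dir, "grid.csv"))
  best <- grid$best
  model <- loaders(best$penalty_weight)
  for (id in names(scenes)) {
    probs <- fcn_predict(model, scenes[[id]]$image)
    det <- extract_points(threshold_softmax(probs, best$softmax_threshold),
                          min_area = cfg$min_area)
    m <- match_points(det, scenes[[id]]$annotation,
                      tolerance = cfg$tolerance)
    render_match_overlay(scenes[[id]]$image, m, det, scenes[[id]]$annotation,
                         file.path(eval_dir, paste0(id, "_match.png")))
  }
  invisible(grid)
}

#' Pipeline stage: survey outputs
#'
#' Classifies per-image detected counts into the range scheme, writes the
#' field-record CSV, the count histogram (CSV + PNG) and, when GPS positions
#' are supplied, the GeoJSON/PNG field map.
#'
#' @param cfg a [pipeline_config()].
#' @param positions optional data.frame `image_id`, `lat`, `lon`, `field`.
#' @param n_steps range steps each side of the average count.
#' @param verbose log a stage line to stderr.
#' @return List with `records`, `scheme`, `histogram`, invisibly.
#' @export
cmd_survey <- function(cfg, positions = NULL, n_steps = 5, verbose = TRUE) {
  log_stage(cfg, "survey", verbose)
  det_csv <- require_artifact(
    file.path(cfg$out_dir, "detections", "detections.csv"), "detect")
  det <- utils::read.csv(det_csv)
  scene_ids <- sub("\\.png$", "",
                   list.files(file.path(cfg$out_dir, "scenes"),
                              pattern = "\\.png$"))
  counts <- vapply(scene_ids, function(id)
    sum(as.character(det$image_id) == id), integer(1))
  avg <- mean(counts)
  if (avg <= 0) avg <- 1  # degenerate: nothing detected anywhere
  scheme <- build_range_scheme(avg, n_steps)
  survey_dir <- file.path(cfg$out_dir, "survey")
  dir.create(survey_dir, showWarnings = FALSE, recursive = TRUE)
  records <- data.frame(image_id = scene_ids, lat = NA_real_,
                        lon = NA_real_, predicted_count = counts)
  if (!is.null(positions)) {
    idx <- match(records$image_id, positions$image_id)
    records$lat <- positions$lat[idx]
    records$lon <- positions$lon[idx]
  }
  records$range_label <- classify_range(records$predicted_count, scheme)
  write_field_records_csv(records, scheme,
                          file.path(survey_dir, "field_records.csv"))
  hist_tab <- range_histogram(counts, scheme,
                              csv_path = file.path(survey_dir, "histogram.csv"),
                              png_path = file.path(survey_dir, "histogram.png"))
  if (!is.null(positions))
    render_field_map(records, scheme,
                     geojson_path = file.path(survey_dir, "field_map.geojson"),
                     png_path = file.path(survey_dir, "field_map.png"))
  invisible(list(records = records, scheme = scheme, histogram = hist_tab))
}
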