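#' Specify a synthetic field scene
#'
#' The generator emulates a top-view patch of a drilled cereal field at an
#' early growth stage: a textured soil background with clutter, grass-like
#' plant sprites of 2-4 elongated curved leaves radiating from a common base
#' pixel (the base is the ground-truth emergence point), and optional
#' distractors — isolated leaf-like strokes and pale residue — that locally
#' resemble emergence points but carry no truth point. Scenes are
#' deterministic given the seed.
#'
#' Sprite and mark sizes are scaled down roughly in proportion to the scene:
#' the default 8-px mark diameter on 128-px scenes with 8-14-px leaves keeps
#' the mark-to-plant ratio of 20-px marks on full-resolution field images.
#'
#' @param image_shape `c(height, width)` pixels (>= 32 each).
#' @param plant_count exact number of plants (>= 0).
#' @param distractor_rate expected distractors per plant (Poisson draw).
#' @param plant_scale `c(min, max)` leaf length, pixels.
#' @param n_leaves range of leaves per plant.
#' @param mark_diameter annotation disk diameter recorded on the truth.
#' @param row_structure `NULL` for uniform placement, or
#'   `list(spacing = , jitter = )` to place plants along vertical drill rows
#'   with lateral jitter (overlap between neighbours rises as jitter falls).
#' @param min_spacing minimum distance between plant bases (0 = unconstrained;
#'   enforced by bounded resampling).
#' @param leaf_color,soil_color mean RGB of foliage and soil.
#' @param noise_sd per-pixel background noise.
#' @param clutter_density soil speckles/stones per 1000 pixels.
#' @param base_nub if `TRUE`, darken a 1.5-px nub where leaves meet the soil
#'   (the visual signature of a real emergence point).
#' @param seed integer seed.
#' @return Object of class `psep_scene_spec`.
#' @export
scene_spec <- function(image_shape = c(128, 128), plant_count = 6,
                       distractor_rate = 0.75, plant_scale = c(8, 14),
                       n_leaves = c(2, 4), mark_diameter = 8,
                       row_structure = NULL, min_spacing = 0,
                       leaf_color = c(0.22, 0.52, 0.18),
                       soil_color = c(0.42, 0.33, 0.24),
                       noise_sd = 0.035, clutter_density = 0.6,
                       base_nub = TRUE, seed = 1) {
  stopifnot(plant_count >= 0, distractor_rate >= 0,
            all(image_shape >= 32))
  structure(
    list(image_shape = as.integer(image_shape[1:2]),
         plant_count = as.integer(plant_count),
         distractor_rate = distractor_rate, plant_scale = plant_scale,
         n_leaves = as.integer(n_leaves), mark_diameter = mark_diameter,
         row_structure = row_structure, min_spacing = min_spacing,
         leaf_color = leaf_color, soil_color = soil_color,
         noise_sd = noise_sd, clutter_density = clutter_density,
         base_nub = base_nub, seed = as.integer(seed)),
    class = "psep_scene_spec")
}

#' Preset scene difficulties
#'
#' `"easy"`: no distractors, well-separated bright plants on calm soil — a
#' pipeline should reach near-perfect detection here. `"hard"`: drill-row
#' placement with overlap, extra background noise and leaf-tip/residue
#' distractors at a rate of 1.2 per plant — the regime in which a plain
#' cross-entropy model produces false positives at distractor sites.
#'
#' @param difficulty `"easy"` or `"hard"`.
#' @param ... overrides passed to [scene_spec()].
#' @return A [scene_spec()].
#' @export
scene_preset <- function(difficulty = c("easy", "hard"), ...) {
  difficulty <- match.arg(difficulty)
  defaults <- switch(difficulty,
    easy = list(distractor_rate = 0, min_spacing = 14,
                leaf_color = c(0.20, 0.62, 0.16), noise_sd = 0.025,
                clutter_density = 0.3),
    hard = list(distractor_rate = 1.2,
                row_structure = list(spacing = 22, jitter = 4),
                min_spacing = 6, noise_sd = 0.045, clutter_density = 0.9))
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_spec, args)
}

#' Generate a synthetic field scene
#'
#' Renders the scene described by `spec`: textured soil, then plant sprites
#' (their base pixels become the ground-truth annotation), then distractors.
#' The realized plant count always equals `spec$plant_count`; identical specs
#' (including seed) give pixel-identical images.
#'
#' @param spec a [scene_spec()].
#' @return Object of class `psep_scene`: `image` (H x W x 3 in `[0, 1]`),
#'   `annotation` ([point_annotation()] of the emergence points),
#'   `distractor_points` (k x 2 matrix, diagnostics only), `spec`.
#' @examples
#' sc <- generate_scene(scene_spec(plant_count = 3, seed = 7))
#' nrow(sc$annotation$points)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "psep_scene_spec"))
  with_seed_(spec$seed, {
    h <- spec$image_shape[1]; w <- spec$image_shape[2]
    img <- soil_background(h, w, spec)
    bases <- sample_bases(spec)
    leaf_len <- spec$plant_scale
    for (i in seq_len(nrow(bases))) {
      img <- draw_plant(img, bases[i, ], spec)
    }
    n_d <- if (spec$distractor_rate > 0)
      stats::rpois(1, spec$distractor_rate * max(spec$plant_count, 1)) else 0L
    dpts <- matrix(numeric(0), 0, 2)
    for (j in seq_len(n_d)) {
      r0 <- stats::runif(1, 2, h - 3)
      c0 <- stats::runif(1, 2, w - 3)
      kind <- stats::runif(1)
      if (kind < 0.5) {
        # weed rosette: short yellow-green leaves radiating from a faint nub —
        # geometrically an emergence point, separable only by hue and scale
        weed_col <- c(0.38, 0.52, 0.12)
        nl <- sample(2:3, 1)
        a0 <- stats::runif(1, 0, 2 * pi)
        for (k in seq_len(nl)) {
          ang <- a0 + (k - 1) * 2 * pi / nl + stats::rnorm(1, 0, 0.35)
          len <- stats::runif(1, 0.55, 0.8) * stats::runif(1, leaf_len[1], leaf_len[2])
          tip <- c(r0 + len * sin(ang), c0 + len * cos(ang))
          bend <- stats::rnorm(2, 0, 0.22 * len)
          col <- pmin(pmax(weed_col + stats::rnorm(3, 0, 0.03), 0), 1)
          img <- draw_leaf_stroke(img, c(r0, c0), tip, bend, col,
                                  width0 = 2.2, width1 = 1)
        }
        img <- draw_disk(img, c(r0, c0), 1.9, weed_col * 0.4, alpha = 0.85)
      } else if (kind < 0.8) {
        # isolated leaf-like stroke: its near end mimics an emergence point
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, leaf_len[1], leaf_len[2])
        tip <- c(r0 + len * sin(ang), c0 + len * cos(ang))
        bend <- stats::rnorm(2, 0, 0.25 * len)
        col <- pmin(pmax(spec$leaf_color + stats::rnorm(3, 0, 0.03), 0), 1)
        img <- draw_leaf_stroke(img, c(r0, c0), tip, bend, col)
      } else {
        # pale straw residue
        ang <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 3, 8)
        tip <- c(r0 + len * sin(ang), c0 + len * cos(ang))
        img <- draw_segment(img, c(r0, c0), tip,
                            c(0.76, 0.68, 0.45) + stats::rnorm(3, 0, 0.02),
                            width = stats::runif(1, 1.5, 2.5))
      }
      dpts <- rbind(dpts, c(r0, c0))
    }
    img <- pmin(pmax(img, 0), 1)
    structure(
      list(image = img,
           annotation = point_annotation(bases, c(h, w),
                                         mark_diameter = spec$mark_diameter),
           distractor_points = dpts, spec = spec),
      class = "psep_scene")
  })
}

#' @export
print.psep_scene <- function(x, ...) {
  cat(sprintf("<psep_scene> %d x %d, %d plant(s), %d distractor(s)\n",
              dim(x$image)[1], dim(x$image)[2], nrow(x$annotation$points),
              nrow(x$distractor_points)))
  invisible(x)
}

soil_background <- function(h, w, spec) {
  img <- array(0, c(h, w, 3))
  # low-frequency tonal blotches from an upsampled coarse noise grid
  coarse <- matrix(stats::rnorm(ceiling(h / 16) * ceiling(w / 16), 0, 0.05),
                   ceiling(h / 16))
  blotch <- coarse[rep(seq_len(nrow(coarse)), each = 16)[1:h],
                   rep(seq_len(ncol(coarse)), each = 16)[1:w]]
  blotch <- blur3(blur3(blotch))
  for (ch in 1:3)
    img[, , ch] <- spec$soil_color[ch] + blotch +
      stats::rnorm(h * w, 0, spec$noise_sd)
  n_clutter <- stats::rpois(1, spec$clutter_density * h * w / 1000)
  for (i in seq_len(n_clutter)) {
    ctr <- c(stats::runif(1, 0, h - 1), stats::runif(1, 0, w - 1))
    shade <- stats::runif(1, -0.12, 0.15)
    img <- draw_disk(img, ctr, stats::runif(1, 0.8, 2.2),
                     pmin(pmax(spec$soil_color + shade, 0), 1),
                     alpha = 0.8)
  }
  img
}

blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[c(1, 1:(h - 1)), ]; dn <- m[c(2:h, h), ]
  lf <- m[, c(1, 1:(w - 1))]; rt <- m[, c(2:w, w)]
  (m + up + dn + lf + rt) / 5
}

sample_bases <- function(spec, max_tries = 200) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  n <- spec$plant_count
  if (n == 0) return(matrix(numeric(0), 0, 2))
  margin <- 2
  rs <- spec$row_structure
  row_cols <- if (!is.null(rs))
    seq(rs$spacing / 2, w - 1 - rs$spacing / 4, by = rs$spacing)
  bases <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (!is.null(rs)) {
        cc <- sample(row_cols, 1) + stats::rnorm(1, 0, rs$jitter)
        cc <- min(max(cc, margin), w - 1 - margin)
        rr <- stats::runif(1, margin, h - 1 - margin)
      } else {
        rr <- stats::runif(1, margin, h - 1 - margin)
        cc <- stats::runif(1, margin, w - 1 - margin)
      }
      if (spec$min_spacing > 0 && i > 1) {
        d <- sqrt((bases[1:(i - 1), 1] - rr)^2 + (bases[1:(i - 1), 2] - cc)^2)
        if (min(d) < spec$min_spacing) next
      }
      bases[i, ] <- c(rr, cc)
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("could not place plant %d after %d tries (min_spacing %g too large for %d plants on %d x %d)",
            i, max_tries, spec$min_spacing, n, h, w)
  }
  bases
}

draw_plant <- function(img, base, spec) {
  nl <- sample(spec$n_leaves[1]:spec$n_leaves[2], 1)
  ang0 <- stats::runif(1, 0, 2 * pi)
  for (k in seq_len(nl)) {
    ang <- ang0 + (k - 1) * 2 * pi / nl + stats::rnorm(1, 0, 0.35)
    len <- stats::runif(1, spec$plant_scale[1], spec$plant_scale[2])
    tip <- c(base[1] + len * sin(ang), base[2] + len * cos(ang))
    bend <- stats::rnorm(2, 0, 0.22 * len)
    col <- pmin(pmax(spec$leaf_color + stats::rnorm(3, 0, 0.04), 0), 1)
    img <- draw_leaf_stroke(img, base, tip, bend, col)
  }
  if (spec$base_nub)
    img <- draw_disk(img, base, 2, spec$leaf_color * 0.4, alpha = 0.95)
  img
}

#' Generate a dataset of scenes
#'
#' Renders one scene per spec. When `dir` is given, scene images are written
#' as PNGs and all truth points as a single annotation CSV in the dialect of
#' [read_annotations_csv()]; scene ids are `"<prefix>_<index>"`.
#'
#' @param specs list of [scene_spec()] objects.
#' @param dir optional output directory (created if needed).
#' @param prefix id/file prefix.
#' @return Named list of [generate_scene()] results.
#' @export
generate_dataset <- function(specs, dir = NULL, prefix = "scene") {
  scenes <- lapply(specs, generate_scene)
  names(scenes) <- sprintf("%s_%03d", prefix, seq_along(scenes))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(scenes))
      png::writePNG(scenes[[id]]$image, file.path(dir, paste0(id, ".png")))
    anns <- lapply(scenes, `[[`, "annotation")
    write_annotations_csv(anns, file.path(dir, "annotations.csv"))
  }
  scenes
}

#' Assemble training samples from scenes
#'
#' Converts scenes into the `(image, label, weights)` triples [fcn_train()]
#' consumes: labels via [rasterize_marks()], weights via
#' [build_weight_mask()] with the given halo and optional per-scene penalty
#' masks.
#'
#' @param scenes list of [generate_scene()] results (or any list with
#'   `image` and `annotation`).
#' @param penalty_masks optional list of penalty masks, parallel to
#'   `scenes`.
#' @param penalty_weight weight applied on penalty pixels.
#' @param halo_radius zero-weight ring width (default: mark radius).
#' @return List of training samples.
#' @export
make_training_set <- function(scenes, penalty_masks = NULL,
                              penalty_weight = 0, halo_radius = NULL) {
  lapply(seq_along(scenes), function(i) {
    s <- scenes[[i]]
    hr <- halo_radius %||% (s$annotation$mark_diameter / 2)
    list(image = s$image,
         label = rasterize_marks(s$annotation),
         weights = build_weight_mask(
           s$annotation,
           penalty = if (!is.null(penalty_masks)) penalty_masks[[i]],
           penalty_weight = penalty_weight, halo_radius = hr))
  })
}
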