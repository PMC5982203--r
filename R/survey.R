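#' Build a count-range scheme
#'
#' Survey maps and stratified evaluation sampling bin per-image PSEP counts
#' into ranges derived from the fields' average count: `n_steps` bins of
#' width `average_count / n_steps` are taken below and above the average,
#' giving `2 * n_steps + 1` labels. Range 0 is the singleton {0}; Range i
#' (i >= 1) covers `((i - 1) * bandwidth, i * bandwidth]`; the top range is
#' open above. With the reference average of 60 and 5 steps the bandwidth is
#' 12 and there are eleven ranges, Range 5 covering 48 < count <= 60.
#'
#' @param average_count mean per-image count across the surveyed fields
#'   (> 0, need not be an integer).
#' @param n_steps bins on each side of the average (default 5).
#' @return Object of class `psep_range_scheme`: `average_count`, `n_steps`,
#'   `bandwidth`, `n_ranges`, and a `breaks` data.frame with the label and
#'   `(lower, upper]` bounds of every range.
#' @examples
#' sc <- build_range_scheme(60, 5)
#' sc$bandwidth  # 12
#' @export
build_range_scheme <- function(average_count, n_steps = 5) {
  if (!(average_count > 0)) stopf("`average_count` must be > 0")
  if (!(n_steps >= 1)) stopf("`n_steps` must be >= 1")
  n_steps <- as.integer(n_steps)
  bw <- average_count / n_steps
  labels <- 0:(2L * n_steps)
  lower <- c(-Inf, pmax(0, (labels[-1] - 1) * bw))
  upper <- c(0, labels[-1] * bw)
  upper[length(upper)] <- Inf
  structure(
    list(average_count = average_count, n_steps = n_steps, bandwidth = bw,
         n_ranges = length(labels),
         breaks = data.frame(label = labels, lower = lower, upper = upper)),
    class = "psep_range_scheme")
}

#' @export
print.psep_range_scheme <- function(x, ...) {
  cat(sprintf("<psep_range_scheme> average %g, %d ranges of bandwidth %g\n",
              x$average_count, x$n_ranges, x$bandwidth))
  invisible(x)
}

#' Classify a count into its range label
#'
#' Vectorized over `count`. A count of 0 maps to Range 0; otherwise label
#' `i` is assigned when `(i - 1) * bandwidth < count <= i * bandwidth`,
#' capped at the open-ended top range.
#'
#' @param count non-negative integer count(s).
#' @param scheme a [build_range_scheme()].
#' @return Integer range label(s) in `0 .. 2 * n_steps`.
#' @examples
#' sc <- build_range_scheme(60, 5)
#' classify_range(c(0, 48, 49, 55, 200), sc)  # 0 4 5 5 10
#' @export
classify_range <- function(count, scheme) {
  stopifnot(inherits(scheme, "psep_range_scheme"))
  if (any(count < 0)) stopf("counts must be non-negative")
  top <- 2L * scheme$n_steps
  lab <- as.integer(ceiling(count / scheme$bandwidth))
  lab[count == 0] <- 0L
  pmin(lab, top)
}

#' Stratified selection of evaluation images
#'
#' Draws up to `per_cell` images uniformly at random from every
#' (field, range) cell, so the evaluation set covers all plant-density ranges
#' in all fields rather than clustering at each field's typical density.
#' Cells with no images contribute nothing. With 3 fields, all 11 ranges
#' occupied and `per_cell = 1`, 33 images are selected.
#'
#' @param records data.frame with at least columns `image_id`, `field` and
#'   either `range_label` or `predicted_count` (classified via `scheme`).
#' @param scheme a [build_range_scheme()] (needed when only counts given).
#' @param per_cell images drawn per (field, range) cell.
#' @param seed RNG seed for the draw.
#' @return Character vector of selected image ids.
#' @export
stratified_select <- function(records, scheme = NULL, per_cell = 1,
                              seed = 1) {
  if (!(per_cell >= 1)) stopf("`per_cell` must be >= 1")
  if (is.null(records$range_label)) {
    if (is.null(scheme)) stopf("need `scheme` when records lack range_label")
    records$range_label <- classify_range(records$predicted_count, scheme)
  }
  with_seed_(seed, {
    picks <- character(0)
    for (f in unique(records$field)) {
      sub_f <- records[records$field == f, , drop = FALSE]
      for (rl in sort(unique(sub_f$range_label))) {
        ids <- as.character(sub_f$image_id[sub_f$range_label == rl])
        k <- min(per_cell, length(ids))
        picks <- c(picks, ids[sample.int(length(ids), k)])
      }
    }
    picks
  })
}

#' Augment annotated images fourfold
#'
#' Expands each annotated image into four variants — the original, its 90
#' degree rotation, its transpose, and the mirrored fourth variant their
#' composition yields — with point annotations transformed consistently
#' (a point at `(r, c)` of an H x W image maps to `(c, r)` under transpose).
#' Applied to 212 annotated images this gives the reference evaluation pool
#' of 848.
#'
#' @param scenes list of samples, each a list with `image` (H x W x C array)
#'   and `annotation` (a [point_annotation()]).
#' @return List of length `4 * length(scenes)` in the same format; variant
#'   tags are appended to names when present.
#' @export
augment_set <- function(scenes) {
  out <- list()
  nm <- names(scenes) %||% as.character(seq_along(scenes))
  for (i in seq_along(scenes)) {
    s <- scenes[[i]]
    h <- dim(s$image)[1]; w <- dim(s$image)[2]
    pts <- s$annotation$points
    variants <- list(
      identity = list(image = s$image, points = pts, shape = c(h, w)),
      rot90 = list(image = rot90_cw(s$image),
                   points = cbind(pts[, 2], h - 1 - pts[, 1]),
                   shape = c(w, h)),
      transpose = list(image = transpose_img(s$image),
                       points = cbind(pts[, 2], pts[, 1]),
                       shape = c(w, h)),
      flip = list(image = flip_horizontal(s$image),
                  points = cbind(pts[, 1], w - 1 - pts[, 2]),
                  shape = c(h, w)))
    for (vn in names(variants)) {
      v <- variants[[vn]]
      out[[paste0(nm[i], "_", vn)]] <- list(
        image = v$image,
        annotation = point_annotation(
          v$points, v$shape, mark_diameter = s$annotation$mark_diameter))
    }
  }
  out
}

# clockwise 90-degree rotation: (r, c) -> (c, H - 1 - r); H x W -> W x H
rot90_cw <- function(img) {
  d <- dim(img)
  aperm(img[d[1]:1, , , drop = FALSE], c(2, 1, 3))
}

transpose_img <- function(img) aperm(img, c(2, 1, 3))

flip_horizontal <- function(img) {
  d <- dim(img)
  img[, d[2]:1, , drop = FALSE]
}

#' Histogram of counts by range
#'
#' Tabulates per-image counts into the scheme's ranges (survey-style density
#' histograms) and optionally writes a CSV and a barplot PNG.
#'
#' @param counts integer vector of per-image counts.
#' @param scheme a [build_range_scheme()].
#' @param csv_path,png_path optional output paths.
#' @return data.frame `range_label`, `n_images` (all ranges, zeros kept).
#' @export
range_histogram <- function(counts, scheme, csv_path = NULL,
                            png_path = NULL) {
  lab <- classify_range(counts, scheme)
  all_lab <- scheme$breaks$label
  tab <- data.frame(range_label = all_lab,
                    n_images = as.integer(table(factor(lab, all_lab))))
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 420)
    graphics::barplot(tab$n_images, names.arg = tab$range_label,
                      xlab = "range", ylab = "images",
                      main = "PSEP count distribution", col = "darkseagreen")
    grDevices::dev.off()
  }
  tab
}

#' Render a geo-referenced field map of predicted counts
#'
#' One marker per image at its GPS position, coloured by the count-range
#' label under a deterministic palette. Writes a GeoJSON FeatureCollection
#' (point features carrying `image_id`, `predicted_count`, `range` properties)
#' and, optionally, a rendered PNG. Records without a position are skipped
#' with a warning.
#'
#' @param records data.frame with columns `image_id`, `lat`, `lon`,
#'   `predicted_count` and optionally `range_label`.
#' @param scheme a [build_range_scheme()] used to (re)derive labels and the
#'   palette.
#' @param geojson_path output GeoJSON path.
#' @param png_path optional rendered map PNG.
#' @return data.frame of the plotted records (with `range_label` and
#'   `color`), invisibly.
#' @export
render_field_map <- function(records, scheme, geojson_path,
                             png_path = NULL) {
  miss <- is.na(records$lat) | is.na(records$lon)
  if (any(miss)) {
    warning(sprintf("%d record(s) without position skipped", sum(miss)))
    records <- records[!miss, , drop = FALSE]
  }
  records$range_label <- classify_range(records$predicted_count, scheme)
  pal <- range_palette(scheme)
  records$color <- pal[records$range_label + 1]
  features <- lapply(seq_len(nrow(records)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(records$lon[i], records$lat[i])),
         properties = list(image_id = as.character(records$image_id[i]),
                           predicted_count = records$predicted_count[i],
                           range = records$range_label[i],
                           color = records$color[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       geojson_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 560)
    if (nrow(records) == 0) {
      graphics::plot.new()
      graphics::title("field map (no records)")
    } else {
      graphics::plot(records$lon, records$lat, pch = 19, cex = 1.4,
                     col = records$color, xlab = "longitude",
                     ylab = "latitude", main = "predicted PSEPs per image")
      graphics::legend("topright", legend = scheme$breaks$label,
                       col = pal, pch = 19, cex = 0.7, title = "range")
    }
    grDevices::dev.off()
  }
  invisible(records)
}

# deterministic palette over range labels: blue (sparse) to red (dense)
range_palette <- function(scheme) {
  n <- scheme$n_ranges
  grDevices::hcl.colors(n, palette = "RdYlBu", rev = TRUE)
}

#' Write field records as CSV
#'
#' Columns `image_id, lat, lon, predicted_count, range_label`.
#'
#' @param records data.frame (labels derived from `scheme` when absent).
#' @param scheme a [build_range_scheme()].
#' @param path output CSV path.
#' @export
write_field_records_csv <- function(records, scheme, path) {
  if (is.null(records$range_label))
    records$range_label <- classify_range(records$predicted_count, scheme)
  utils::write.csv(
    records[, c("image_id", "lat", "lon", "predicted_count", "range_label")],
    path, row.names = FALSE)
  invisible(path)
}
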