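#' Point annotation of plant stem emerging points
#'
#' Bundles a set of annotated emergence points with the disk diameter used to
#' mark them and the shape of the annotated image. Coordinates are 0-based
#' `(row, col)` pixel-center positions; fractional coordinates are allowed
#' (e.g. centroids recovered from an overlay layer).
#'
#' @param points numeric matrix (or data.frame) with two columns `row`, `col`,
#'   one annotated point per row; may have zero rows.
#' @param image_shape integer vector `c(height, width)` in pixels.
#' @param mark_diameter diameter in pixels of the filled disk drawn at each
#'   point when rasterizing (default 20, the marking convention the model is
#'   trained against).
#' @return An object of class `psep_annotation` with elements `points`
#'   (n x 2 numeric matrix), `image_shape`, `mark_diameter`.
#' @examples
#' ann <- point_annotation(cbind(c(50, 10), c(50, 90)), c(100, 100))
#' ann$mark_diameter
#' @export
point_annotation <- function(points, image_shape, mark_diameter = 20) {
  if (is.null(points) || NROW(points) == 0) {
    pts <- matrix(numeric(0), 0, 2)
  } else {
    pts <- as.matrix(points)
    if (ncol(pts) != 2) stopf("`points` must have two columns (row, col)")
    storage.mode(pts) <- "double"
  }
  colnames(pts) <- c("row", "col")
  image_shape <- as.integer(image_shape[1:2])
  if (any(image_shape < 1)) stopf("`image_shape` must be positive")
  if (!(mark_diameter > 0)) stopf("`mark_diameter` must be > 0")
  if (nrow(pts) > 0) {
    bad <- pts[, 1] < 0 | pts[, 1] > image_shape[1] - 1 |
      pts[, 2] < 0 | pts[, 2] > image_shape[2] - 1
    if (any(bad))
      stopf("%d point(s) fall outside the %d x %d image",
            sum(bad), image_shape[1], image_shape[2])
  }
  structure(
    list(points = pts, image_shape = image_shape,
         mark_diameter = as.numeric(mark_diameter)),
    class = "psep_annotation")
}

#' @export
print.psep_annotation <- function(x, ...) {
  cat(sprintf("<psep_annotation> %d point(s), image %d x %d, mark diameter %g px\n",
              nrow(x$points), x$image_shape[1], x$image_shape[2],
              x$mark_diameter))
  invisible(x)
}

#' Read and write point-annotation CSV files
#'
#' The on-disk dialect is a CSV with columns `image_id,row,col` (0-based
#' pixel coordinates). `read_annotations_csv()` returns a named list of
#' [point_annotation()] objects, one per `image_id`; image ids listed in
#' `image_shapes` but absent from the CSV yield empty annotations.
#'
#' @param path CSV file path.
#' @param image_shapes named list (or single `c(h, w)` applied to all ids) of
#'   image shapes keyed by image id.
#' @param mark_diameter disk diameter passed through to [point_annotation()].
#' @return Named list of `psep_annotation` objects.
#' @export
read_annotations_csv <- function(path, image_shapes, mark_diameter = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "row", "col")
  if (!all(need %in% names(df)))
    stopf("annotation CSV must have columns image_id,row,col")
  if (!is.list(image_shapes)) {
    ids <- unique(as.character(df$image_id))
    image_shapes <- stats::setNames(rep(list(image_shapes), length(ids)), ids)
  }
  out <- lapply(names(image_shapes), function(id) {
    sub <- df[as.character(df$image_id) == id, , drop = FALSE]
    point_annotation(cbind(sub$row, sub$col), image_shapes[[id]],
                     mark_diameter = mark_diameter)
  })
  stats::setNames(out, names(image_shapes))
}

#' @rdname read_annotations_csv
#' @param annotations named list of `psep_annotation` objects.
#' @export
write_annotations_csv <- function(annotations, path) {
  rows <- lapply(names(annotations), function(id) {
    pts <- annotations[[id]]$points
    if (nrow(pts) == 0) return(NULL)
    data.frame(image_id = id, row = pts[, 1], col = pts[, 2])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(image_id = character(0),
                                    row = numeric(0), col = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Recover point annotations from a red-mark overlay layer
#'
#' Annotators mark emergence points by painting filled red circles on a
#' separate transparent layer. This parses such a layer back into point
#' coordinates: pixels within `color_tolerance` (per-channel distance) of pure
#' red (255, 0, 0) are selected, grouped into 8-connected components, and one
#' point is returned at each component centroid.
#'
#' Components much more elongated than a disk (ratio of principal axes above
#' `eccentricity_threshold`) trigger a warning, since they suggest stray brush
#' strokes rather than circular marks; the centroid is still returned.
#'
#' @param overlay H x W x 3 (or x4, alpha ignored except as transparency) array
#'   in `[0, 1]`, or a path to a PNG file.
#' @param mark_diameter diameter recorded on the returned annotation.
#' @param color_tolerance maximum per-channel distance from pure red, on the
#'   0-255 scale (default 30).
#' @param eccentricity_threshold axis-ratio above which a component is flagged
#'   as non-disk-like (default 3).
#' @return A [point_annotation()] with one point per red component (possibly
#'   zero points).
#' @export
parse_overlay_layer <- function(overlay, mark_diameter = 20,
                                color_tolerance = 30,
                                eccentricity_threshold = 3) {
  if (is.character(overlay)) overlay <- png::readPNG(overlay)
  if (length(dim(overlay)) != 3 || !(dim(overlay)[3] %in% c(3L, 4L)))
    stopf("`overlay` must be an H x W x 3 or H x W x 4 array")
  h <- dim(overlay)[1]; w <- dim(overlay)[2]
  tol <- color_tolerance / 255
  red <- abs(overlay[, , 1] - 1) <= tol &
    overlay[, , 2] <= tol & overlay[, , 3] <= tol
  if (dim(overlay)[3] == 4L) red <- red & overlay[, , 4] > 0
  if (!any(red))
    return(point_annotation(NULL, c(h, w), mark_diameter = mark_diameter))
  lab <- label_components(red)
  pts <- component_centroids(lab)$points
  # flag stray non-circular marks
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < 4) next
    cv <- stats::cov(idx)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] > 0 && sqrt(ev[1] / ev[2]) > eccentricity_threshold)
      warning(sprintf("overlay component %d is not disk-like (axis ratio %.1f); using its centroid anyway",
                      k, sqrt(ev[1] / ev[2])))
  }
  point_annotation(pts, c(h, w), mark_diameter = mark_diameter)
}
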