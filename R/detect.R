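#' Threshold the PSEP softmax channel
#'
#' Marks a pixel as detected when its PSEP-class probability reaches the
#' softmax threshold. Model selection sweeps thresholds 0.1 to 0.9 in steps of
#' 0.1.
#'
#' @param probs H x W x 2 probability array (or H x W PSEP-probability
#'   matrix).
#' @param threshold probability cutoff, strictly inside (0, 1).
#' @return Logical H x W matrix of class `psep_binmap` with attribute
#'   `threshold`.
#' @export
threshold_softmax <- function(probs, threshold) {
  if (!(is.numeric(threshold) && length(threshold) == 1 &&
        threshold > 0 && threshold < 1))
    stopf("`threshold` must be a single probability in (0, 1)")
  pp <- psep_prob_channel(probs)
  bm <- pp >= threshold
  attr(bm, "threshold") <- threshold
  class(bm) <- c("psep_binmap", class(bm))
  bm
}

# 8-connected component labelling. EBImage::bwlabel() labels 4-connected
# components; components touching only diagonally are then merged with a small
# union-find over the label graph. Labels are renumbered 1..n in order of
# first appearance (column-major).
label_components <- function(mask) {
  mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  parent <- seq_len(nlab)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    for (i in which(keep)) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  if (h > 1 && w > 1) {
    union_pairs(lab[-h, -w], lab[-1, -1])  # down-right diagonal
    union_pairs(lab[-h, -1], lab[-1, -w])  # down-left diagonal
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  # renumber roots consecutively, preserving first-appearance order
  newid <- integer(nlab)
  newid[sort(unique(root))] <- seq_along(unique(root))
  out <- lab
  pos <- lab > 0L
  out[pos] <- newid[root[lab[pos]]]
  out
}

# 0-based centroids (unweighted coordinate means) and sizes per component
component_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0) return(list(points = matrix(numeric(0), 0, 2),
                          sizes = integer(0)))
  idx <- which(lab > 0L, arr.ind = TRUE)
  g <- lab[lab > 0L]
  sums <- rowsum(cbind(idx[, 1], idx[, 2]), g)
  cnt <- as.integer(rowsum(rep(1L, length(g)), g))
  pts <- sums / cnt - 1  # to 0-based pixel-center coordinates
  colnames(pts) <- c("row", "col")
  list(points = pts, sizes = cnt)
}

#' Extract detection points from a binary map
#'
#' Groups positive pixels into 8-connected components and reports one
#' detection per component at the unweighted mean of its pixel coordinates
#' (0-based). Annotated marks are filled disks whose center is the intended
#' location, so the centroid — not the peak probability — is the natural point
#' estimate. A minimum component area can prune speckle.
#'
#' @param bmap logical matrix, e.g. from [threshold_softmax()].
#' @param min_area smallest component (pixels) kept (default 1 = keep all).
#' @return Object of class `psep_detections`: list with `points` (n x 2
#'   matrix of `(row, col)` centroids), `component_sizes`, and the originating
#'   `threshold` when known.
#' @export
extract_points <- function(bmap, min_area = 1) {
  lab <- label_components(bmap)
  cc <- component_centroids(lab)
  keep <- cc$sizes >= min_area
  structure(
    list(points = cc$points[keep, , drop = FALSE],
         component_sizes = cc$sizes[keep],
         threshold = attr(bmap, "threshold")),
    class = "psep_detections")
}

#' @export
print.psep_detections <- function(x, ...) {
  cat(sprintf("<psep_detections> %d point(s)%s\n", nrow(x$points),
              if (!is.null(x$threshold))
                sprintf(" at softmax threshold %g", x$threshold) else ""))
  invisible(x)
}

#' Write detections as CSV
#'
#' One row per detection: `image_id,row,col,component_size,threshold`.
#'
#' @param detections named list of `psep_detections` keyed by image id (or a
#'   single object, with `image_id` supplied).
#' @param path output CSV path.
#' @param image_id id used when `detections` is a single object.
#' @export
write_detections_csv <- function(detections, path, image_id = "image") {
  if (inherits(detections, "psep_detections"))
    detections <- stats::setNames(list(detections), image_id)
  rows <- lapply(names(detections), function(id) {
    det <- detections[[id]]
    if (nrow(det$points) == 0) return(NULL)
    data.frame(image_id = id, row = det$points[, 1], col = det$points[, 2],
               component_size = det$component_sizes,
               threshold = det$threshold %||% NA_real_)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(image_id = character(0), row = numeric(0),
                     col = numeric(0), component_size = integer(0),
                     threshold = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
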