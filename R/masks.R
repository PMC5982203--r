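#' Rasterize point marks into a disk label mask
#'
#' Draws a filled disk of diameter `mark_diameter` around each annotated point:
#' a pixel is labelled 1 (PSEP) when its center lies within `mark_diameter / 2`
#' (Euclidean, boundary inclusive) of any point, and 0 (background) elsewhere.
#' Overlapping disks merge. The result is the per-pixel training target from
#' which the one-hot coding of the loss is derived.
#'
#' @param annotation a [point_annotation()].
#' @return Integer H x W matrix of class `psep_label` with entries 0/1.
#' @examples
#' ann <- point_annotation(cbind(50, 50), c(100, 100))
#' lab <- rasterize_marks(ann)
#' sum(lab)  # pixels within radius 10 of (50, 50)
#' @export
rasterize_marks <- function(annotation) {
  stopifnot(inherits(annotation, "psep_annotation"))
  h <- annotation$image_shape[1]; w <- annotation$image_shape[2]
  r <- annotation$mark_diameter / 2
  d2 <- nearest_point_dist2(annotation$points, c(h, w), within = ceiling(r) + 1)
  lab <- matrix(0L, h, w)
  lab[d2 <= r^2] <- 1L
  class(lab) <- c("psep_label", class(lab))
  lab
}

#' Derive penalty regions from a baseline model's false positives
#'
#' After an initial network is trained without penalties, its residual false
#' positives (leaf tips, weeds, plant residue that resemble emergence points)
#' define *penalty regions*: places where misclassification is up-weighted
#' when retraining. A pixel enters the penalty region when the baseline
#' PSEP probability reaches `prob_threshold` **and** the pixel lies farther
#' than `exclusion_radius` from every annotated point, so that responses on or
#' near true marks (which are correct, or near-misses the halo forgives) are
#' never penalized.
#'
#' @param baseline_probs H x W x 2 probability array from [fcn_predict()] (or
#'   an H x W matrix of PSEP probabilities).
#' @param annotation the [point_annotation()] for the same image.
#' @param exclusion_radius minimum distance (pixels, from each annotated point
#'   center) a penalty pixel must keep; default mark radius + halo radius
#'   (= `mark_diameter`), which keeps penalty regions disjoint from both the
#'   mark disks and the non-punishing halo.
#' @param prob_threshold baseline PSEP probability at or above which a pixel
#'   counts as a fault response (default 0.5).
#' @return Logical H x W matrix of class `psep_penalty`.
#' @export
derive_penalty_regions <- function(baseline_probs, annotation,
                                   exclusion_radius = annotation$mark_diameter,
                                   prob_threshold = 0.5) {
  stopifnot(inherits(annotation, "psep_annotation"))
  pp <- psep_prob_channel(baseline_probs)
  h <- annotation$image_shape[1]; w <- annotation$image_shape[2]
  if (!identical(dim(pp), c(h, w)))
    stopf("`baseline_probs` (%d x %d) does not match the annotated image (%d x %d)",
          dim(pp)[1], dim(pp)[2], h, w)
  pen <- pp >= prob_threshold
  if (nrow(annotation$points) > 0 && any(pen)) {
    d2 <- nearest_point_dist2(annotation$points, c(h, w),
                              within = ceiling(exclusion_radius) + 1)
    pen <- pen & (d2 > exclusion_radius^2)
  }
  class(pen) <- c("psep_penalty", class(pen))
  pen
}

# Accept either an H x W x 2 softmax array (channel 2 = PSEP) or a plain
# H x W probability matrix.
psep_prob_channel <- function(probs) {
  if (length(dim(probs)) == 3) {
    if (dim(probs)[3] < 2) stopf("probability array must have 2 channels")
    return(probs[, , 2])
  }
  as.matrix(probs)
}

#' Assemble the per-pixel loss weight mask
#'
#' Builds the weight \eqn{p_n} of the penalty-weighted cross-entropy: 0 on the
#' non-punishing halo ring around each annotated point (radii in
#' `(mark_radius, mark_radius + halo_radius]`), `penalty_weight` on penalty
#' pixels, and 1 everywhere else, including inside the mark disks. The halo
#' takes precedence over penalty pixels, so weight levels are exactly
#' `{0, 1, penalty_weight}`.
#'
#' The halo absorbs annotation jitter: a prediction a few pixels off an
#' annotated point incurs no loss there, steering the network towards the
#' marked location without punishing near-misses.
#'
#' @param annotation a [point_annotation()].
#' @param penalty logical H x W penalty-region mask from
#'   [derive_penalty_regions()], or `NULL` for none.
#' @param penalty_weight weight applied on penalty pixels (>= 0; the grid in
#'   model selection uses 0, 50 and 75).
#' @param halo_radius width in pixels of the zero-weight ring beyond the mark
#'   disk (default: the mark radius).
#' @return Numeric H x W matrix of class `psep_weights` with attribute
#'   `penalty_weight`.
#' @export
build_weight_mask <- function(annotation, penalty = NULL, penalty_weight = 0,
                              halo_radius = annotation$mark_diameter / 2) {
  stopifnot(inherits(annotation, "psep_annotation"))
  if (penalty_weight < 0) stopf("`penalty_weight` must be >= 0")
  h <- annotation$image_shape[1]; w <- annotation$image_shape[2]
  wts <- matrix(1, h, w)
  if (!is.null(penalty)) {
    check_shape2(wts, penalty, "weight mask", "penalty mask")
    wts[penalty] <- penalty_weight
  }
  if (nrow(annotation$points) > 0 && halo_radius > 0) {
    r_in <- annotation$mark_diameter / 2
    r_out <- r_in + halo_radius
    d2 <- nearest_point_dist2(annotation$points, c(h, w),
                              within = ceiling(r_out) + 1)
    wts[d2 > r_in^2 & d2 <= r_out^2] <- 0
  }
  attr(wts, "penalty_weight") <- penalty_weight
  class(wts) <- c("psep_weights", class(wts))
  wts
}

#' Write and read encoded mask PNGs
#'
#' Masks are exchanged as single-channel PNGs with the integer encoding
#' 0 = background, 1 = PSEP disk, 2 = penalty region and, in the extended
#' debug encoding, 3 = non-punishing halo (halo pixels otherwise fold into
#' background). Values are stored in the 8-bit grey channel directly
#' (grey level = code / 255).
#'
#' @param label 0/1 label matrix from [rasterize_marks()].
#' @param penalty optional logical penalty mask.
#' @param halo optional logical halo mask (written as 3 when `debug = TRUE`).
#' @param path output PNG path.
#' @param debug include the halo as code 3.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns an integer matrix of codes.
#' @export
write_mask_png <- function(label, path, penalty = NULL, halo = NULL,
                           debug = FALSE) {
  code <- matrix(as.integer(label), nrow(label), ncol(label))
  if (!is.null(penalty)) code[penalty & code == 0L] <- 2L
  if (debug && !is.null(halo)) code[halo & code == 0L] <- 3L
  png::writePNG(code / 255, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3) g <- g[, , 1]
  matrix(as.integer(round(g * 255)), nrow(g), ncol(g))
}

# Convenience: halo ring mask (0-weight region) for an annotation.
halo_mask <- function(annotation, halo_radius = annotation$mark_diameter / 2) {
  h <- annotation$image_shape[1]; w <- annotation$image_shape[2]
  r_in <- annotation$mark_diameter / 2
  r_out <- r_in + halo_radius
  d2 <- nearest_point_dist2(annotation$points, c(h, w),
                            within = ceiling(r_out) + 1)
  d2 > r_in^2 & d2 <= r_out^2
}
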