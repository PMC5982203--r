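# Independent oracles used across tests.

# Brute-force one-to-one point matching: enumerate every partial injective
# assignment of detections to annotations with all pair distances <= tol,
# maximize the number of pairs, then minimize total distance. Exponential;
# for <= 6 x 6 points only.
brute_force_match <- function(dp, ap, tol) {
  nd <- nrow(dp); na <- nrow(ap)
  if (nd == 0 || na == 0)
    return(list(TP = 0L, total = 0))
  dmat <- sqrt(outer(dp[, 1], ap[, 1], `-`)^2 +
               outer(dp[, 2], ap[, 2], `-`)^2)
  best <- list(TP = -1L, total = Inf)
  used <- rep(FALSE, na)
  recurse <- function(i, tp, tot) {
    if (i > nd) {
      if (tp > best$TP || (tp == best$TP && tot < best$total))
        best <<- list(TP = tp, total = tot)
      return(invisible())
    }
    recurse(i + 1, tp, tot)  # detection i unmatched
    for (j in seq_len(na)) {
      if (!used[j] && dmat[i, j] <= tol) {
        used[j] <<- TRUE
        recurse(i + 1, tp + 1L, tot + dmat[i, j])
        used[j] <<- FALSE
      }
    }
  }
  recurse(1L, 0L, 0)
  best
}

# False positives of `model` lying within `tol` of a distractor site,
# totalled over scenes.
count_fp_at_distractors <- function(model, scenes, threshold, tol) {
  tot <- 0L
  for (s in scenes) {
    det <- extract_points(threshold_softmax(fcn_predict(model, s$image),
                                            threshold))
    m <- match_points(det, s$annotation, tolerance = tol)
    fp_idx <- setdiff(seq_len(nrow(det$points)), m$pairs$detection)
    if (length(fp_idx) && nrow(s$distractor_points)) {
      dd <- sqrt(outer(det$points[fp_idx, 1, drop = TRUE],
                       s$distractor_points[, 1], `-`)^2 +
                 outer(det$points[fp_idx, 2, drop = TRUE],
                       s$distractor_points[, 2], `-`)^2)
      tot <- tot + sum(apply(matrix(dd, nrow = length(fp_idx)), 1, min) <= tol)
    }
  }
  tot
}

# Hard/easy scene batches with per-scene plant counts drawn reproducibly.
make_scene_batch <- function(n, difficulty, seed0, counts = NULL, ...) {
  if (is.null(counts)) {
    set.seed(seed0)
    counts <- sample(3:12, n, replace = TRUE)
  }
  lapply(seq_len(n), function(i)
    generate_scene(scene_preset(difficulty, plant_count = counts[i],
                                seed = seed0 + i, ...)))
}
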