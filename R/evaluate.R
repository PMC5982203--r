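#' Match detections to annotations one-to-one
#'
#' Pairs detected points with annotated points under a distance tolerance.
#' Among all one-to-one assignments whose every pair lies within `tolerance`
#' pixels (Euclidean), the matching maximizes the number of pairs first and
#' minimizes the total paired distance second. Matched detections are true
#' positives (TP), unmatched detections false positives (FP) and unmatched
#' annotations false negatives (FN, i.e. missed points).
#'
#' The optimum is found by solving a minimum-cost linear assignment (a compact
#' Hungarian/shortest-augmenting-path solver) on a cost matrix in which
#' out-of-tolerance pairs and dummy partners carry a cost larger than any
#' total within-tolerance distance, which makes cost minimization
#' lexicographic in (pair count, total distance).
#'
#' @param detections a [extract_points()] result, or an n x 2 `(row, col)`
#'   matrix.
#' @param annotations a [point_annotation()], or an m x 2 matrix.
#' @param tolerance maximum pairing distance in pixels (> 0); the default 20
#'   pairs points whose 20-px mark disks could touch.
#' @return Object of class `psep_match`: `pairs` (data.frame `detection`,
#'   `annotation`, `distance`), counts `TP`, `FP`, `FN`, and `tolerance`.
#' @examples
#' m <- match_points(rbind(c(0, 0), c(10, 10)), rbind(c(1, 1)), tolerance = 5)
#' c(m$TP, m$FP, m$FN)
#' @export
match_points <- function(detections, annotations, tolerance = 20) {
  if (!(tolerance > 0)) stopf("`tolerance` must be > 0")
  dp <- as_points_matrix(detections)
  ap <- as_points_matrix(annotations)
  nd <- nrow(dp); na <- nrow(ap)
  empty <- data.frame(detection = integer(0), annotation = integer(0),
                      distance = numeric(0))
  if (nd == 0 || na == 0) {
    return(structure(list(pairs = empty, TP = 0L, FP = nd, FN = na,
                          tolerance = tolerance), class = "psep_match"))
  }
  dmat <- sqrt(outer(dp[, 1], ap[, 1], `-`)^2 +
               outer(dp[, 2], ap[, 2], `-`)^2)
  s <- max(nd, na)
  pen <- (s + 1) * (tolerance + 1)
  cost <- matrix(pen, s, s)
  ok <- dmat <= tolerance
  cost[seq_len(nd), seq_len(na)][ok] <- dmat[ok]
  assign_col_row <- solve_assignment(cost)
  pairs <- empty
  for (j in seq_len(s)) {
    i <- assign_col_row[j]
    if (i <= nd && j <= na && cost[i, j] < pen)
      pairs <- rbind(pairs, data.frame(detection = i, annotation = j,
                                       distance = dmat[i, j]))
  }
  structure(list(pairs = pairs, TP = nrow(pairs), FP = nd - nrow(pairs),
                 FN = na - nrow(pairs), tolerance = tolerance),
            class = "psep_match")
}

as_points_matrix <- function(x) {
  if (inherits(x, "psep_detections")) return(x$points)
  if (inherits(x, "psep_annotation")) return(x$points)
  if (is.null(x) || NROW(x) == 0) return(matrix(numeric(0), 0, 2))
  m <- as.matrix(x)
  if (ncol(m) != 2) stopf("point sets must have two columns (row, col)")
  m
}

#' @export
print.psep_match <- function(x, ...) {
  cat(sprintf("<psep_match> TP=%d FP=%d FN=%d (tolerance %g px)\n",
              x$TP, x$FP, x$FN, x$tolerance))
  invisible(x)
}

# Minimum-cost assignment on a square cost matrix (Hungarian algorithm,
# shortest-augmenting-path formulation with potentials, O(n^3)).
# Returns an integer vector r of length n: column j is assigned to row r[j].
solve_assignment <- function(a) {
  n <- nrow(a)
  stopifnot(ncol(a) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j + 1]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      cand <- a[i0, ] - u[i0 + 1] - v[2:(n + 1)]
      free <- !used[2:(n + 1)]
      upd <- free & cand < minv[2:(n + 1)]
      if (any(upd)) {
        minv[2:(n + 1)][upd] <- cand[upd]
        way[2:(n + 1)][upd] <- j0
      }
      mfree <- minv[2:(n + 1)]
      mfree[!free] <- Inf
      j1 <- which.min(mfree)
      delta <- mfree[j1]
      iu <- which(used)
      u[p[iu] + 1] <- u[p[iu] + 1] + delta
      v[iu] <- v[iu] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[2:(n + 1)]
}

#' Precision, recall and F1 from a point matching
#'
#' Precision \eqn{P = TP / (TP + FP)}, recall \eqn{R = TP / (TP + FN)} and
#' their harmonic mean \eqn{F = 2PR / (P + R)}. Empty denominators follow the
#' perfect-on-empty convention: with no detections \eqn{P = 1}, with no
#' annotations \eqn{R = 1}, and \eqn{F = 0} whenever \eqn{P} or \eqn{R} is 0.
#'
#' @param match a [match_points()] result, or a list with elements `TP`,
#'   `FP`, `FN`.
#' @param penalty_weight,softmax_threshold optional metadata carried into the
#'   record (used by [grid_evaluate()]).
#' @return Object of class `psep_metrics`: list with `P`, `R`, `F`, counts
#'   and metadata.
#' @examples
#' compute_metrics(list(TP = 48, FP = 6, FN = 7))
#' @export
compute_metrics <- function(match, penalty_weight = NA_real_,
                            softmax_threshold = NA_real_) {
  tp <- match$TP; fp <- match$FP; fn <- match$FN
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f <- if (p == 0 || r == 0) 0 else 2 * p * r / (p + r)
  structure(list(P = p, R = r, F = f, TP = tp, FP = fp, FN = fn,
                 penalty_weight = penalty_weight,
                 softmax_threshold = softmax_threshold),
            class = "psep_metrics")
}

#' @export
print.psep_metrics <- function(x, ...) {
  cat(sprintf("<psep_metrics> P=%.4f R=%.4f F=%.4f (TP=%d FP=%d FN=%d)\n",
              x$P, x$R, x$F, x$TP, x$FP, x$FN))
  invisible(x)
}

#' Sweep the penalty-weight x softmax-threshold model grid
#'
#' Trains one model per penalty weight (via the caller-supplied `train_fn`)
#' and evaluates each at every softmax threshold, producing one
#' precision/recall/F record per grid cell — with the reference settings of 3
#' weights and 9 thresholds, a collection of 27 models. Counts are pooled
#' over the evaluation images (micro-averaged) before computing metrics. The
#' best cell maximizes F; ties resolve to the lowest threshold (favouring
#' recall), then the lowest weight.
#'
#' @param train_fn function `(penalty_weight) -> psep_fcn model` (or any
#'   object accepted by `predict_fn`).
#' @param eval_set list of evaluation samples, each a list with `image` and
#'   `annotation` (a [point_annotation()]).
#' @param weights penalty weights to train at (default `c(0, 50, 75)`).
#' @param thresholds softmax thresholds (default `seq(0.1, 0.9, by = 0.1)`).
#' @param tolerance matching tolerance in pixels.
#' @param min_area minimum detection component area.
#' @param predict_fn function `(model, image) -> H x W x 2 probs`; defaults
#'   to [fcn_predict()].
#' @return Object of class `psep_grid`: `table` (data.frame `penalty_weight`,
#'   `softmax_threshold`, `P`, `R`, `F`, `TP`, `FP`, `FN`) and `best` (the
#'   selected row).
#' @export
grid_evaluate <- function(train_fn, eval_set, weights = c(0, 50, 75),
                          thresholds = seq(0.1, 0.9, by = 0.1),
                          tolerance = 20, min_area = 1,
                          predict_fn = fcn_predict) {
  if (length(weights) == 0 || length(thresholds) == 0)
    stopf("`weights` and `thresholds` must be non-empty")
  rows <- list()
  for (wt in weights) {
    model <- train_fn(wt)
    probs <- lapply(eval_set, function(s) predict_fn(model, s$image))
    for (th in thresholds) {
      tp <- fp <- fn <- 0L
      for (i in seq_along(eval_set)) {
        det <- extract_points(threshold_softmax(probs[[i]], th),
                              min_area = min_area)
        m <- match_points(det, eval_set[[i]]$annotation,
                          tolerance = tolerance)
        tp <- tp + m$TP; fp <- fp + m$FP; fn <- fn + m$FN
      }
      met <- compute_metrics(list(TP = tp, FP = fp, FN = fn))
      rows[[length(rows) + 1]] <- data.frame(
        penalty_weight = wt, softmax_threshold = th,
        P = met$P, R = met$R, F = met$F, TP = tp, FP = fp, FN = fn)
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$F, tab$softmax_threshold, tab$penalty_weight)
  structure(list(table = tab, best = tab[ord[1], ]), class = "psep_grid")
}

#' @export
print.psep_grid <- function(x, ...) {
  cat(sprintf("<psep_grid> %d cells; best: weight %g, threshold %g, F=%.4f\n",
              nrow(x$table), x$best$penalty_weight, x$best$softmax_threshold,
              x$best$F))
  invisible(x)
}

#' @rdname grid_evaluate
#' @param grid a `psep_grid`.
#' @param path output CSV path.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(grid$table[, c("penalty_weight", "softmax_threshold",
                                  "P", "R", "F")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Coefficient of determination between predicted and annotated counts
#'
#' Measures how well per-image predicted PSEP counts recover the annotated
#' counts: \eqn{R^2 = 1 - \sum_i (\hat y_i - y_i)^2 / \sum_i (y_i - \bar y)^2}
#' with \eqn{y} the annotated counts. Equals 1 when predictions are exact and
#' 0 when they are no better than the annotated mean.
#'
#' @param predicted_counts numeric vector of predicted counts.
#' @param annotated_counts numeric vector of ground-truth counts (same
#'   length, n >= 2, non-constant).
#' @return The coefficient of determination (may be negative for predictions
#'   worse than the mean).
#' @export
count_regression <- function(predicted_counts, annotated_counts) {
  if (length(predicted_counts) != length(annotated_counts))
    stopf("count vectors must have equal length")
  n <- length(annotated_counts)
  if (n < 2) stopf("need at least 2 images")
  ss_tot <- sum((annotated_counts - mean(annotated_counts))^2)
  if (ss_tot == 0) stopf("annotated counts have zero variance")
  1 - sum((predicted_counts - annotated_counts)^2) / ss_tot
}

#' Render a match visualization PNG
#'
#' Paints the standard colour code over the image: pink disks for true
#' predictions (matched pairs, with a white line joining detection and
#' annotation), blue for false detections and red for missed annotations.
#'
#' @param image H x W x 3 array in `[0, 1]` (grey background used if `NULL`).
#' @param match a [match_points()] result.
#' @param detections,annotations the point sets that produced `match`.
#' @param path output PNG path.
#' @param radius dot radius in pixels.
#' @return `path`, invisibly.
#' @export
render_match_overlay <- function(image, match, detections, annotations, path,
                                 radius = 4) {
  dp <- as_points_matrix(detections)
  ap <- as_points_matrix(annotations)
  if (is.null(image)) {
    hw <- ceiling(apply(rbind(dp, ap, c(32, 32)), 2, max)) + 16
    image <- array(0.5, c(hw[1], hw[2], 3))
  }
  img <- image
  pink <- c(1, 0.41, 0.71); blue <- c(0.12, 0.35, 1); red <- c(1, 0, 0)
  mt <- match$pairs
  for (r in seq_len(nrow(mt))) {
    img <- draw_segment(img, dp[mt$detection[r], ], ap[mt$annotation[r], ],
                        c(1, 1, 1), width = 1)
  }
  for (i in setdiff(seq_len(nrow(dp)), mt$detection))
    img <- draw_disk(img, dp[i, ], radius, blue)
  for (j in setdiff(seq_len(nrow(ap)), mt$annotation))
    img <- draw_disk(img, ap[j, ], radius, red)
  for (r in seq_len(nrow(mt))) {
    img <- draw_disk(img, dp[mt$detection[r], ], radius, pink)
    img <- draw_disk(img, ap[mt$annotation[r], ], radius, pink)
  }
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
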