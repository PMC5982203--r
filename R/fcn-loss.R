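#' Penalty-weighted cross-entropy loss
#'
#' The training objective is a per-pixel cross-entropy in which each pixel
#' carries its own weight \eqn{p_n} from the weight mask:
#' \deqn{E = -\frac{1}{K} \sum_{n=1}^{N} \sum_{k=1}^{K} p_n\, t_{nk} \ln y_{nk}}
#' where \eqn{N} is the pixel count, \eqn{K = 2} the number of classes,
#' \eqn{t_{nk}} the one-hot target from the label mask and \eqn{y_{nk}} the
#' softmax output. Halo pixels (\eqn{p_n = 0}) contribute nothing; penalty
#' pixels contribute \eqn{p_n} times the ordinary loss, focusing training on
#' regions a baseline model got wrong.
#'
#' With `literal_scaling = TRUE` the \eqn{1/K} constant is applied exactly as
#' written above, so the value grows with image size. The default
#' (`FALSE`) divides additionally by \eqn{\sum_n p_n}, giving a weighted mean
#' that is comparable across crop sizes; the two differ only by a positive
#' constant for a fixed weight mask, so gradients point the same way.
#'
#' @param probs H x W x 2 probability array (e.g. from [fcn_predict()]).
#' @param label 0/1 H x W label matrix ([rasterize_marks()]).
#' @param weights non-negative H x W weight matrix ([build_weight_mask()]);
#'   `NULL` means all ones.
#' @param literal_scaling if `TRUE`, report the plain `1/K`-scaled sum.
#' @param eps probabilities are clipped to `[eps, 1]` before the logarithm.
#' @return Non-negative scalar loss.
#' @examples
#' p <- array(0.5, c(1, 1, 2))
#' lab <- matrix(1L, 1, 1)
#' weighted_cross_entropy(p, lab, literal_scaling = TRUE)  # -(1/2) log(0.5)
#' @export
weighted_cross_entropy <- function(probs, label, weights = NULL,
                                   literal_scaling = FALSE, eps = 1e-7) {
  d <- dim(probs)
  if (length(d) != 3 || d[3] != 2)
    stopf("`probs` must be an H x W x 2 array")
  check_shape2(probs, label, "probs", "label")
  if (is.null(weights)) weights <- matrix(1, d[1], d[2])
  check_shape2(probs, weights, "probs", "weights")
  if (any(probs < 0) || any(probs > 1))
    stopf("probabilities must lie in [0, 1]")
  if (any(weights < 0)) stopf("weights must be non-negative")
  k <- 2
  y_t <- ifelse(label == 1L, probs[, , 2], probs[, , 1])
  e <- -sum(weights * log(pmax(y_t, eps))) / k
  if (!literal_scaling) {
    sw <- sum(weights)
    e <- if (sw > 0) e / sw else 0
  }
  e
}

# d(loss)/d(logits) for softmax + weighted cross-entropy, on the padded grid.
# `probs_pad` are padded softmax outputs; label/weights live on the original
# (cropped) grid and the gradient is zero on padding.
wce_grad_logits <- function(probs_pad, label, weights, pad_hw,
                            literal_scaling = FALSE) {
  h <- nrow(label); w <- ncol(label)
  k <- 2
  t2 <- array(0, c(pad_hw[1], pad_hw[2], 2))
  w2 <- matrix(0, pad_hw[1], pad_hw[2])
  t2[seq_len(h), seq_len(w), 1] <- as.numeric(label == 0L)
  t2[seq_len(h), seq_len(w), 2] <- as.numeric(label == 1L)
  w2[seq_len(h), seq_len(w)] <- weights
  scale <- 1 / k
  if (!literal_scaling) {
    sw <- sum(weights)
    scale <- if (sw > 0) scale / sw else 0
  }
  dz <- probs_pad - t2
  mask_pad <- matrix(0, pad_hw[1], pad_hw[2])
  mask_pad[seq_len(h), seq_len(w)] <- 1
  dz[, , 1] <- dz[, , 1] * w2 * scale * mask_pad
  dz[, , 2] <- dz[, , 2] * w2 * scale * mask_pad
  dz
}
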