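#' Training schedule
#'
#' Defaults follow the reference training recipe: 40 epochs of Adagrad at an
#' initial learning rate of 1e-3, halved after epochs 32 and 36, with random
#' square crops each epoch to curb overfitting. For the desk-scale `mini`
#' backbone trained from scratch, shorter schedules with a larger initial rate
#' are typical (see the package vignette); every field is configurable.
#'
#' @param epochs number of passes over the dataset.
#' @param initial_lr Adagrad learning rate.
#' @param lr_drop_epochs epochs after which the rate is divided by
#'   `lr_drop_factor` (cumulative).
#' @param lr_drop_factor division factor at each drop.
#' @param crop_size side of the random square crop, or `NULL` for full images.
#' @param seed integer seed driving shuffling and crop positions.
#' @return An object of class `psep_schedule`.
#' @examples
#' sch <- training_schedule()
#' schedule_lr(sch, 33)  # 5e-4
#' @export
training_schedule <- function(epochs = 40, initial_lr = 1e-3,
                              lr_drop_epochs = c(32, 36), lr_drop_factor = 2,
                              crop_size = 1500, seed = 1) {
  stopifnot(epochs >= 1, initial_lr > 0, lr_drop_factor > 0)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_drop_epochs = as.integer(lr_drop_epochs),
                 lr_drop_factor = lr_drop_factor,
                 crop_size = if (!is.null(crop_size)) as.integer(crop_size),
                 seed = as.integer(seed)),
            class = "psep_schedule")
}

#' @rdname training_schedule
#' @param schedule a `psep_schedule`.
#' @param epoch 1-based epoch number.
#' @return `schedule_lr()`: the learning rate in force during `epoch`.
#' @export
schedule_lr <- function(schedule, epoch) {
  drops <- sum(epoch > schedule$lr_drop_epochs)
  schedule$initial_lr / schedule$lr_drop_factor^drops
}

#' Train a segmentation network
#'
#' Stochastic training with one Adagrad update per image: each epoch shuffles
#' the dataset, draws a fresh random crop per image (when `crop_size` is set
#' and smaller than the image), runs the forward pass, evaluates the
#' penalty-weighted cross-entropy and backpropagates. All randomness (shuffle
#' order, crop positions) is drawn from a stream seeded by `schedule$seed`, so
#' identical seed + data reproduce the loss trajectory exactly on a
#' fixed-threading run.
#'
#' @param model a [fcn_build()] model (updated copy is returned).
#' @param dataset list of training samples, each a list with elements `image`
#'   (H x W x 3 array), `label` (0/1 matrix) and `weights` (non-negative
#'   matrix, `NULL` for all ones).
#' @param schedule a [training_schedule()].
#' @param literal_scaling passed to the loss; the default `FALSE` optimizes
#'   the weighted-mean form.
#' @param verbose print one line per epoch.
#' @return List with `model` (trained) and `log`, a data.frame with columns
#'   `epoch`, `lr`, `mean_loss`.
#' @export
fcn_train <- function(model, dataset, schedule = training_schedule(),
                      literal_scaling = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "psep_fcn"), inherits(schedule, "psep_schedule"))
  if (length(dataset) == 0) stopf("`dataset` is empty")
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    d <- dim(s$image)
    if (!is.null(schedule$crop_size) &&
        (schedule$crop_size > d[1] || schedule$crop_size > d[2]))
      stopf("crop_size %d exceeds image %d (%d x %d)",
            schedule$crop_size, i, d[1], d[2])
    check_shape2(s$image, s$label, "image", "label")
  }
  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    mean_loss = numeric(0))
  with_seed_(schedule$seed, {
    for (epoch in seq_len(schedule$epochs)) {
      lr <- schedule_lr(schedule, epoch)
      ord <- sample.int(length(dataset))
      losses <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        s <- dataset[[ord[ii]]]
        img <- s$image; lab <- s$label
        wts <- s$weights %||% matrix(1, nrow(lab), ncol(lab))
        cs <- schedule$crop_size
        d <- dim(img)
        if (!is.null(cs) && (cs < d[1] || cs < d[2])) {
          r0 <- sample.int(d[1] - cs + 1L, 1L)
          c0 <- sample.int(d[2] - cs + 1L, 1L)
          img <- img[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L), , drop = FALSE]
          lab <- lab[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)]
          wts <- wts[r0:(r0 + cs - 1L), c0:(c0 + cs - 1L)]
        }
        fw <- fcn_forward(model, img, training = TRUE)
        losses[ii] <- weighted_cross_entropy(fw$probs, lab, wts,
                                             literal_scaling = literal_scaling)
        dz <- wce_grad_logits(fw$probs_pad, lab, wts, fw$pad_hw,
                              literal_scaling = literal_scaling)
        grads <- fcn_backward(model, fw, dz)
        model <- adagrad_update(model, grads, lr)
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   mean_loss = mean(losses)))
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  mean loss %.5f",
                        epoch, lr, mean(losses)))
    }
  })
  list(model = model, log = log)
}

adagrad_update <- function(model, grads, lr, eps = 1e-8) {
  upd_one <- function(p, g, s) {
    s2 <- s + g * g
    list(p = p - lr * g / (sqrt(s2) + eps), s = s2)
  }
  for (s in seq_along(model$params$stages)) {
    for (j in seq_along(model$params$stages[[s]])) {
      for (nm in c("W", "b")) {
        u <- upd_one(model$params$stages[[s]][[j]][[nm]],
                     grads$stages[[s]][[j]][[nm]],
                     model$state$stages[[s]][[j]][[nm]])
        model$params$stages[[s]][[j]][[nm]] <- u$p
        model$state$stages[[s]][[j]][[nm]] <- u$s
      }
    }
  }
  score_parms <- if (isFALSE(model$spec$score_bias)) "W" else c("W", "b")
  for (key in names(model$params$scores)) {
    for (nm in score_parms) {
      u <- upd_one(model$params$scores[[key]][[nm]],
                   grads$scores[[key]][[nm]],
                   model$state$scores[[key]][[nm]])
      model$params$scores[[key]][[nm]] <- u$p
      model$state$scores[[key]][[nm]] <- u$s
    }
  }
  model
}

#' Write a per-epoch loss log as CSV
#'
#' @param log data.frame from [fcn_train()] (`epoch`, `lr`, `mean_loss`).
#' @param path output CSV path.
#' @export
write_loss_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
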