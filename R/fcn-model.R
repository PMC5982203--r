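#' Specify a fully-convolutional segmentation network
#'
#' The network follows the FCN-8s pattern: a convolutional backbone whose
#' stages each halve the spatial resolution, a coarse 1x1-convolution class
#' score at the deepest stage, and skip fusion — the coarse score is upsampled
#' x2 and summed with a 1x1 score of the next-shallower stage, twice, before a
#' final upsampling to input resolution and a per-pixel two-way softmax
#' (background vs. PSEP).
#'
#' Two backbones are provided. `"mini"` has three downsampling stages with few
#' channels, so skip fusion runs at strides 8, 4 and 2; it trains in minutes
#' on a CPU and is the backbone used throughout the examples and tests.
#' `"vgg16-fcn8s"` reproduces the classical 5-stage VGG16 topology (fusion at
#' strides 32, 16 and 8); `channel_scale` shrinks its channel counts for
#' experimentation — pretrained weights are not bundled.
#'
#' @param backbone `"mini"` or `"vgg16-fcn8s"`.
#' @param num_classes number of output classes (2: background, PSEP).
#' @param channel_scale multiplier on backbone channel counts (vgg only).
#' @param min_input smallest accepted input side, in pixels (default 32).
#' @return An object of class `psep_fcn_spec`.
#' @examples
#' fcn_spec("mini")
#' @export
fcn_spec <- function(backbone = c("mini", "vgg16-fcn8s"), num_classes = 2,
                     channel_scale = 1, min_input = 32) {
  backbone <- match.arg(backbone)
  stages <- switch(backbone,
    "mini" = list(12L, 24L, c(32L, 32L)),
    "vgg16-fcn8s" = lapply(
      list(c(64, 64), c(128, 128), c(256, 256, 256),
           c(512, 512, 512), c(512, 512, 512)),
      function(ch) pmax(1L, as.integer(round(ch * channel_scale)))))
  n <- length(stages)
  structure(
    list(backbone = backbone, stages = stages, num_classes = num_classes,
         min_input = as.integer(min_input), n_stages = n,
         skip_strides = as.integer(2^((n - 2L):n)), score_bias = FALSE),
    class = "psep_fcn_spec")
}

#' @export
print.psep_fcn_spec <- function(x, ...) {
  cat(sprintf("<psep_fcn_spec> backbone=%s, %d stages, skip fusion at strides %s\n",
              x$backbone, x$n_stages,
              paste(rev(x$skip_strides), collapse = "/")))
  invisible(x)
}

#' Build (initialize) a segmentation network
#'
#' Allocates He-initialized weights for the backbone convolutions and
#' small-variance weights for the 1x1 class-score convolutions, together with
#' the Adagrad accumulator state. All randomness derives from `seed`.
#'
#' @param spec a [fcn_spec()].
#' @param seed integer seed controlling weight initialization.
#' @param in_channels input image channels (3 for RGB).
#' @return An object of class `psep_fcn`.
#' @export
fcn_build <- function(spec = fcn_spec(), seed = 1, in_channels = 3) {
  stopifnot(inherits(spec, "psep_fcn_spec"))
  with_seed_(seed, {
    params <- list(stages = list(), scores = list())
    cin <- in_channels
    for (s in seq_along(spec$stages)) {
      convs <- list()
      for (cout in spec$stages[[s]]) {
        k <- 3L
        sd <- sqrt(2 / (k * k * cin))
        convs[[length(convs) + 1]] <- list(
          W = matrix(stats::rnorm(k * k * cin * cout, sd = sd),
                     k * k * cin, cout),
          b = rep(0, cout), k = k)
        cin <- cout
      }
      params$stages[[s]] <- convs
    }
    n <- spec$n_stages
    for (t in (n - 2L):n) {
      cfeat <- utils::tail(spec$stages[[t]], 1)
      params$scores[[as.character(t)]] <- list(
        W = matrix(stats::rnorm(cfeat * spec$num_classes, sd = 0.01),
                   cfeat, spec$num_classes),
        b = rep(0, spec$num_classes), k = 1L)
    }
    model <- list(spec = spec, params = params,
                  state = zero_like_params(params), in_channels = in_channels,
                  seed = seed)
    class(model) <- "psep_fcn"
    model
  })
}

zero_like_params <- function(params) {
  rapply(params, function(x) if (is.numeric(x)) x * 0 else x,
         how = "replace")
}

#' @export
print.psep_fcn <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<psep_fcn> backbone=%s, %d parameters\n",
              x$spec$backbone, np))
  invisible(x)
}

check_input_image <- function(model, image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3)
    stopf("`image` must be an H x W x C array")
  if (d[1] < model$spec$min_input || d[2] < model$spec$min_input)
    stopf("input %d x %d is smaller than the minimum accepted size %d x %d",
          d[1], d[2], model$spec$min_input, model$spec$min_input)
  if (d[3] != model$in_channels)
    stopf("input has %d channels, model expects %d", d[3], model$in_channels)
  invisible(TRUE)
}

# Full forward pass. Returns probs cropped to the input size plus, when
# training, all caches needed by fcn_backward().
fcn_forward <- function(model, image, training = FALSE) {
  check_input_image(model, image)
  sp <- model$spec
  n <- sp$n_stages
  d0 <- dim(image)
  x <- pad_to_multiple(image, 2L^n)
  caches <- list(stages = vector("list", n), scores = list())
  feats <- vector("list", n)
  cur <- x
  for (s in seq_len(n)) {
    convs <- model$params$stages[[s]]
    ccache <- vector("list", length(convs))
    for (j in seq_along(convs)) {
      cv <- convs[[j]]
      cf <- conv_fwd(cur, cv$W, cv$b, cv$k, training = training)
      rf <- relu_fwd(cf$out)
      cur <- rf$out
      if (training) ccache[[j]] <- list(conv = cf, mask = rf$mask)
    }
    pf <- maxpool_fwd(cur, training = training)
    cur <- pf$out
    feats[[s]] <- cur
    if (training) caches$stages[[s]] <- list(convs = ccache, pool = pf)
  }
  # coarse score at the deepest stage, then two skip fusions
  sc <- NULL
  for (t in n:(n - 2L)) {
    key <- as.character(t)
    pv <- model$params$scores[[key]]
    sf <- conv_fwd(feats[[t]], pv$W, pv$b, 1L, training = training)
    if (training) caches$scores[[key]] <- sf
    sc <- if (t == n) sf$out else upsample2_fwd(sc) + sf$out
  }
  for (i in seq_len(n - 2L)) sc <- upsample2_fwd(sc)
  probs <- softmax2(sc)
  out <- probs[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE]
  if (!training) return(list(probs = out))
  list(probs = out, probs_pad = probs, caches = caches, feats = feats,
       orig_hw = d0[1:2], pad_hw = dim(x)[1:2])
}

# Backward pass from d(loss)/d(logits) on the padded grid; returns gradients
# shaped like model$params.
fcn_backward <- function(model, fw, dz) {
  sp <- model$spec
  n <- sp$n_stages
  grads <- list(stages = vector("list", n), scores = list())
  for (i in seq_len(n - 2L)) dz <- upsample2_bwd(dz)
  dfeat <- vector("list", n)
  # reverse the fusion chain: dz arrives at stride 2^(n-2)
  for (t in (n - 2L):n) {
    key <- as.character(t)
    pv <- model$params$scores[[key]]
    cb <- conv_bwd(dz, fw$caches$scores[[key]], pv$W, 1L, need_dx = TRUE)
    grads$scores[[key]] <- list(W = cb$dW, b = cb$db)
    dfeat[[t]] <- cb$dx
    if (t < n) dz <- upsample2_bwd(dz)
  }
  dcur <- NULL
  for (s in n:1) {
    d <- dfeat[[s]]
    if (!is.null(dcur)) d <- d + dcur
    d <- maxpool_bwd(d, fw$caches$stages[[s]]$pool)
    convs <- model$params$stages[[s]]
    gconvs <- vector("list", length(convs))
    for (j in rev(seq_along(convs))) {
      cc <- fw$caches$stages[[s]]$convs[[j]]
      d <- relu_bwd(d, cc$mask)
      need_dx <- !(s == 1 && j == 1)
      cb <- conv_bwd(d, cc$conv, convs[[j]]$W, convs[[j]]$k,
                     need_dx = need_dx)
      gconvs[[j]] <- list(W = cb$dW, b = cb$db)
      d <- cb$dx
    }
    grads$stages[[s]] <- gconvs
    dcur <- d
  }
  grads
}

#' Run the network on an image
#'
#' Forward pass only: maps an H x W x 3 image (sides >= the spec's
#' `min_input`, values in \[0, 1\]) to an H x W x 2 array of per-pixel class
#' probabilities (channel 1 background, channel 2 PSEP). Fully convolutional:
#' any accepted input size works, and the output matches the input spatially.
#'
#' @param model a trained or freshly built [fcn_build()] model.
#' @param image H x W x 3 array in `[0, 1]`.
#' @return H x W x 2 probability array; channels sum to 1 per pixel.
#' @export
fcn_predict <- function(model, image) {
  stopifnot(inherits(model, "psep_fcn"))
  fcn_forward(model, image, training = FALSE)$probs
}

#' Save and load model checkpoints
#'
#' The weights go into an RDS file; a human-readable JSON sidecar
#' (`<path>.json`) records the backbone, stage widths, seed and any training
#' schedule metadata so a checkpoint is self-describing.
#'
#' @param model a `psep_fcn` model.
#' @param path checkpoint path (`.rds`).
#' @param schedule optional [training_schedule()] stored as metadata.
#' @return `fcn_save()` returns `path` invisibly; `fcn_load()` the model.
#' @export
fcn_save <- function(model, path, schedule = NULL) {
  saveRDS(model, path)
  meta <- list(backbone = model$spec$backbone,
               stages = model$spec$stages,
               num_classes = model$spec$num_classes,
               seed = model$seed,
               schedule = if (!is.null(schedule)) unclass(schedule))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname fcn_save
#' @export
fcn_load <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "psep_fcn"))
  model
}
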