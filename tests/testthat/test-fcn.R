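test_that("the network is fully convolutional with softmax outputs", {
  model <- fcn_build(fcn_spec("mini"), seed = 1)
  p1 <- fcn_predict(model, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_identical(dim(p1), c(64L, 64L, 2L))
  p2 <- fcn_predict(model, array(runif(33 * 47 * 3), c(33, 47, 3)))
  expect_identical(dim(p2), c(33L, 47L, 2L))
  expect_lt(max(abs(p2[, , 1] + p2[, , 2] - 1)), 1e-6)
  expect_true(all(p2 >= 0 & p2 <= 1))
  # deterministic forward pass
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  expect_identical(fcn_predict(model, img), fcn_predict(model, img))
  expect_error(fcn_predict(model, array(0, c(31, 40, 3))), "minimum")
})

test_that("the vgg16-fcn8s topology builds and fuses at strides 32/16/8", {
  spec <- fcn_spec("vgg16-fcn8s", channel_scale = 1 / 16)
  expect_identical(spec$skip_strides, c(8L, 16L, 32L))
  model <- fcn_build(spec, seed = 2)
  p <- fcn_predict(model, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_identical(dim(p), c(64L, 64L, 2L))
})

test_that("weighted cross-entropy reproduces hand-computed values", {
  # single pixel, target PSEP, y_PSEP = 0.5, p = 1, literal 1/K scaling
  p <- array(c(0.5, 0.5), c(1, 1, 2))
  lab <- matrix(1L, 1, 1)
  e1 <- weighted_cross_entropy(p, lab, matrix(1, 1, 1),
                               literal_scaling = TRUE)
  expect_equal(e1, -0.5 * log(0.5), tolerance = 1e-12)

  # linear in the pixel weight
  e50 <- weighted_cross_entropy(p, lab, matrix(50, 1, 1),
                                literal_scaling = TRUE)
  expect_equal(e50, 50 * e1, tolerance = 1e-12)

  # zero-weight (halo) pixel contributes nothing however wrong
  bad <- array(c(1, 0), c(1, 1, 2))  # confidently background, target PSEP
  expect_identical(weighted_cross_entropy(bad, lab, matrix(0, 1, 1),
                                          literal_scaling = TRUE), 0)

  # perfect one-hot predictions give exactly zero loss
  h <- 8; w <- 8
  lab2 <- matrix(rbinom(h * w, 1, 0.3), h, w)
  perfect <- array(0, c(h, w, 2))
  perfect[, , 1] <- 1 - lab2; perfect[, , 2] <- lab2
  expect_identical(
    weighted_cross_entropy(perfect, lab2, literal_scaling = TRUE), 0)
})

test_that("with unit weights the loss equals plain cross-entropy / K", {
  set.seed(11)
  for (i in 1:5) {
    z <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
    probs <- psep:::softmax2(z)
    lab <- matrix(rbinom(256, 1, 0.4), 16, 16)
    # independent textbook implementation, both one-hot terms spelled out
    t1 <- 1 - lab; t2 <- lab
    plain <- -sum(t1 * log(probs[, , 1]) + t2 * log(probs[, , 2]))
    expect_equal(weighted_cross_entropy(probs, lab, literal_scaling = TRUE),
                 plain / 2, tolerance = 1e-10)
  }
})

test_that("loss is monotone in the penalty weight and in the target prob", {
  # a misclassified penalty pixel makes the loss non-decreasing in weight
  probs <- array(c(0.3, 0.7), c(1, 1, 2))  # fires PSEP
  lab <- matrix(0L, 1, 1)                  # truly background
  es <- sapply(c(0, 50, 75), function(wt)
    weighted_cross_entropy(probs, lab, matrix(wt, 1, 1),
                           literal_scaling = TRUE))
  expect_true(all(diff(es) > 0))

  # pixelwise strictly decreasing in the target-class probability
  ys <- seq(0.1, 0.9, 0.1)
  ls <- sapply(ys, function(y)
    weighted_cross_entropy(array(c(1 - y, y), c(1, 1, 2)), matrix(1L, 1, 1),
                           literal_scaling = TRUE))
  expect_true(all(diff(ls) < 0))
})

test_that("halo pixels have exactly zero gradient", {
  model <- fcn_build(fcn_spec("mini"), seed = 5)
  set.seed(5)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  lab <- matrix(0L, 40, 40); lab[18:22, 18:22] <- 1L
  wts <- matrix(1, 40, 40)
  halo_px <- rbind(c(5, 5), c(30, 12))
  wts[halo_px] <- 0
  fw <- psep:::fcn_forward(model, img, training = TRUE)
  dz <- psep:::wce_grad_logits(fw$probs_pad, lab, wts, fw$pad_hw)
  expect_identical(dz[5, 5, ], c(0, 0))
  expect_identical(dz[30, 12, ], c(0, 0))
  # finite difference: perturbing the probability at a halo pixel leaves E unchanged
  probs <- fw$probs
  e0 <- weighted_cross_entropy(probs, lab, wts)
  probs[5, 5, ] <- c(0.999, 0.001)
  expect_identical(weighted_cross_entropy(probs, lab, wts), e0)
})

test_that("analytic gradients match finite differences through the net", {
  model <- fcn_build(fcn_spec("mini"), seed = 3)
  set.seed(42)
  img <- array(runif(40 * 48 * 3), c(40, 48, 3))
  lab <- matrix(0L, 40, 48); lab[10:14, 10:14] <- 1L
  wts <- matrix(runif(40 * 48, 0, 2), 40, 48)
  fw <- psep:::fcn_forward(model, img, training = TRUE)
  dz <- psep:::wce_grad_logits(fw$probs_pad, lab, wts, fw$pad_hw)
  gr <- psep:::fcn_backward(model, fw, dz)
  eps <- 1e-6
  fd_at <- function(mutate) {
    mp <- mutate(model, eps); mm <- mutate(model, -eps)
    (weighted_cross_entropy(psep:::fcn_forward(mp, img)$probs, lab, wts) -
     weighted_cross_entropy(psep:::fcn_forward(mm, img)$probs, lab, wts)) /
      (2 * eps)
  }
  for (i in c(1, 7)) {
    fd <- fd_at(function(m, e) {
      m$params$stages[[1]][[1]]$W[i] <- m$params$stages[[1]][[1]]$W[i] + e; m
    })
    expect_equal(gr$stages[[1]][[1]]$W[i], fd, tolerance = 1e-4)
  }
  fd <- fd_at(function(m, e) {
    m$params$scores[["3"]]$W[2] <- m$params$scores[["3"]]$W[2] + e; m
  })
  expect_equal(gr$scores[["3"]]$W[2], fd, tolerance = 1e-4)
})

test_that("the learning-rate schedule halves after the drop epochs", {
  sch <- training_schedule()  # 40 epochs, 1e-3, drops after 32 and 36
  expect_identical(schedule_lr(sch, 32), 1e-3)
  expect_identical(schedule_lr(sch, 33), 5e-4)
  expect_identical(schedule_lr(sch, 36), 5e-4)
  expect_identical(schedule_lr(sch, 37), 2.5e-4)
})

test_that("training is seeded-deterministic and reduces the loss", {
  set.seed(9)
  scenes <- lapply(1:6, function(i)
    generate_scene(scene_preset("easy", image_shape = c(64, 64),
                                plant_count = 3, plant_scale = c(6, 9),
                                mark_diameter = 6, min_spacing = 10,
                                seed = 50 + i)))
  tset <- make_training_set(scenes)
  sch <- training_schedule(epochs = 4, initial_lr = 0.05,
                           lr_drop_epochs = c(3, 4), crop_size = NULL,
                           seed = 7)
  f1 <- fcn_train(fcn_build(fcn_spec("mini"), seed = 7), tset, sch)
  f2 <- fcn_train(fcn_build(fcn_spec("mini"), seed = 7), tset, sch)
  expect_identical(f1$log, f2$log)
  img <- scenes[[1]]$image
  expect_identical(fcn_predict(f1$model, img), fcn_predict(f2$model, img))
  expect_lt(f1$log$mean_loss[4], f1$log$mean_loss[1])

  expect_error(fcn_train(fcn_build(fcn_spec("mini")), list(), sch), "empty")
  big_crop <- training_schedule(epochs = 1, crop_size = 128, seed = 1)
  expect_error(fcn_train(fcn_build(fcn_spec("mini")), tset, big_crop),
               "crop")
})

test_that("random crops honour the schedule and keep shapes aligned", {
  set.seed(10)
  scenes <- lapply(1:3, function(i)
    generate_scene(scene_preset("easy", image_shape = c(64, 64),
                                plant_count = 2, plant_scale = c(6, 9),
                                mark_diameter = 6, seed = 80 + i)))
  tset <- make_training_set(scenes)
  sch <- training_schedule(epochs = 2, initial_lr = 0.05,
                           lr_drop_epochs = integer(0), crop_size = 48,
                           seed = 2)
  fit <- fcn_train(fcn_build(fcn_spec("mini"), seed = 2), tset, sch)
  expect_identical(nrow(fit$log), 2L)
  expect_true(all(is.finite(fit$log$mean_loss)))
})

test_that("checkpoints round-trip through save/load with a JSON sidecar", {
  model <- fcn_build(fcn_spec("mini"), seed = 4)
  path <- tempfile(fileext = ".rds")
  fcn_save(model, path, schedule = training_schedule())
  m2 <- fcn_load(path)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  expect_identical(fcn_predict(model, img), fcn_predict(m2, img))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$backbone, "mini")
  expect_identical(meta$schedule$epochs, 40L)
})
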