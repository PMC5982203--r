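test_that("match_points handles exact, out-of-tolerance and empty inputs", {
  pts <- cbind(c(5, 20, 40), c(5, 25, 10))
  m <- match_points(pts, pts, tolerance = 5)
  expect_identical(c(m$TP, m$FP, m$FN), c(3L, 0L, 0L))
  expect_equal(sum(m$pairs$distance), 0)

  m2 <- match_points(cbind(0, 0), cbind(0, 6), tolerance = 5)
  expect_identical(c(m2$TP, m2$FP, m2$FN), c(0L, 1L, 1L))

  m3 <- match_points(matrix(numeric(0), 0, 2), cbind(1, 1), tolerance = 5)
  expect_identical(c(m3$TP, m3$FP, m3$FN), c(0L, 0L, 1L))
  m4 <- match_points(cbind(1, 1), NULL, tolerance = 5)
  expect_identical(c(m4$TP, m4$FP, m4$FN), c(0L, 1L, 0L))

  expect_error(match_points(pts, pts, tolerance = 0), "tolerance")

  # greedy nearest-first is suboptimal here; optimal assignment is required:
  # det1 is nearest to ann1, but pairing det1-ann1 leaves det2 unmatched
  det <- rbind(c(0, 0), c(0, 3))
  ann <- rbind(c(0, 1), c(0, -2.5))
  mo <- match_points(det, ann, tolerance = 3)
  expect_identical(mo$TP, 2L)
})

test_that("match_points equals the brute-force assignment oracle", {
  set.seed(123)
  for (trial in 1:60) {
    nd <- sample(0:6, 1); na <- sample(0:6, 1)
    dp <- cbind(runif(nd, 0, 50), runif(nd, 0, 50))
    ap <- cbind(runif(na, 0, 50), runif(na, 0, 50))
    tol <- sample(c(5, 15, 40), 1)
    got <- match_points(dp, ap, tolerance = tol)
    want <- brute_force_match(dp, ap, tol)
    expect_identical(got$TP, max(want$TP, 0L))
    if (got$TP > 0)
      expect_equal(sum(got$pairs$distance), want$total, tolerance = 1e-9)
    expect_identical(got$TP + got$FP, nd)
    expect_identical(got$TP + got$FN, na)
    expect_true(all(got$pairs$distance <= tol))
  }
})

test_that("swapping detections and annotations swaps FP and FN", {
  set.seed(7)
  dp <- cbind(runif(5, 0, 30), runif(5, 0, 30))
  ap <- cbind(runif(3, 0, 30), runif(3, 0, 30))
  m1 <- match_points(dp, ap, tolerance = 10)
  m2 <- match_points(ap, dp, tolerance = 10)
  expect_identical(m1$TP, m2$TP)
  expect_identical(m1$FP, m2$FN)
  expect_identical(m1$FN, m2$FP)
})

test_that("precision/recall/F follow their formulas and conventions", {
  met <- compute_metrics(list(TP = 48, FP = 6, FN = 7))
  expect_equal(met$P, 48 / 54, tolerance = 1e-12)
  expect_equal(met$R, 48 / 55, tolerance = 1e-12)
  expect_equal(met$F, 2 * met$P * met$R / (met$P + met$R), tolerance = 1e-12)

  # perfect-on-empty conventions
  expect_identical(unlist(compute_metrics(list(TP = 0, FP = 0, FN = 0))[c("P", "R", "F")]),
                   c(P = 1, R = 1, F = 1))
  expect_identical(compute_metrics(list(TP = 0, FP = 3, FN = 0))$F, 0)

  # P = R implies F = P (harmonic-mean identity)
  met2 <- compute_metrics(list(TP = 10, FP = 5, FN = 5))
  expect_equal(met2$F, met2$P, tolerance = 1e-12)

  # F is monotone in TP with FP, FN held fixed
  fs <- sapply(1:20, function(tp)
    compute_metrics(list(TP = tp, FP = 4, FN = 6))$F)
  expect_true(all(diff(fs) > 0))
})

test_that("grid_evaluate enumerates weights x thresholds and picks best", {
  # synthetic stand-in model: probability maps precomputed per scene; the
  # trainer tags the weight so sharper maps mimic a better model
  set.seed(21)
  ann <- point_annotation(rbind(c(10, 10), c(25, 30)), c(40, 40),
                          mark_diameter = 6)
  pm <- matrix(0, 40, 40)
  pm[9:12, 9:12] <- 0.45; pm[24:27, 29:32] <- 0.85
  pm[35:36, 5:6] <- 0.45  # spurious blob, pruned at higher thresholds
  eval_set <- list(list(image = pm, annotation = ann))
  fake_predict <- function(model, image) image
  g <- grid_evaluate(function(w) NULL, eval_set,
                     weights = c(0, 50, 75),
                     thresholds = seq(0.1, 0.9, by = 0.1),
                     tolerance = 6, predict_fn = fake_predict)
  expect_identical(nrow(g$table), 27L)
  g1 <- grid_evaluate(function(w) NULL, eval_set, weights = 0,
                      thresholds = 0.5, tolerance = 6,
                      predict_fn = fake_predict)
  expect_identical(nrow(g1$table), 1L)
  # reproducible under re-run
  g2 <- grid_evaluate(function(w) NULL, eval_set,
                      weights = c(0, 50, 75),
                      thresholds = seq(0.1, 0.9, by = 0.1),
                      tolerance = 6, predict_fn = fake_predict)
  expect_identical(g$table, g2$table)
  # ties on F resolve to the lowest threshold
  top <- g$table[g$table$F == max(g$table$F), ]
  expect_identical(g$best$softmax_threshold, min(top$softmax_threshold))
  expect_error(grid_evaluate(function(w) NULL, eval_set, weights = numeric(0),
                             thresholds = 0.5), "non-empty")
})

test_that("count_regression matches the closed-form R-squared", {
  expect_identical(count_regression(1:10, 1:10), 1)
  ann <- c(2, 4, 6, 8, 10)
  expect_identical(count_regression(rep(mean(ann), 5), ann), 0)

  pred <- c(3, 4, 7, 9, 12, 18, 22, 25, 31, 33)
  annot <- c(2, 5, 8, 10, 13, 17, 21, 27, 30, 35)
  # independent closed form
  r2 <- 1 - sum((pred - annot)^2) / sum((annot - mean(annot))^2)
  expect_equal(count_regression(pred, annot), r2, tolerance = 1e-12)

  expect_error(count_regression(1, 1), "at least 2")
  expect_error(count_regression(c(1, 2), c(3, 3)), "variance")
  expect_error(count_regression(1:3, 1:4), "equal length")
})

test_that("match overlays are rendered with one marker per point", {
  det <- rbind(c(10, 10), c(30, 35))
  ann <- rbind(c(11, 11), c(50, 50))
  m <- match_points(det, ann, tolerance = 5)
  path <- tempfile(fileext = ".png")
  render_match_overlay(NULL, m, det, ann, path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_identical(length(dim(img)), 3L)
})
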