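test_that("rasterize_marks draws inclusive Euclidean disks that merge", {
  # no marks -> empty mask
  empty <- rasterize_marks(point_annotation(NULL, c(100, 100)))
  expect_identical(sum(empty), 0L)
  expect_identical(dim(empty), c(100L, 100L))

  ann <- point_annotation(cbind(50, 50), c(100, 100), mark_diameter = 20)
  lab <- rasterize_marks(ann)
  expect_identical(lab[51, 51], 1L)   # center (distance 0)
  expect_identical(lab[51, 66], 0L)   # (50, 65): distance 15 > radius 10
  expect_identical(lab[51, 61], 1L)   # (50, 60): distance 10, boundary inclusive

  # exhaustive per-pixel distance oracle for the 1-pixel count
  grid <- expand.grid(r = 0:99, c = 0:99)
  oracle <- sum((grid$r - 50)^2 + (grid$c - 50)^2 <= 10^2)
  expect_identical(sum(lab), as.integer(oracle))

  # overlapping disks merge: union count, not sum
  ann2 <- point_annotation(rbind(c(50, 50), c(50, 55)), c(100, 100))
  lab2 <- rasterize_marks(ann2)
  oracle2 <- sum(pmin((grid$r - 50)^2 + (grid$c - 50)^2,
                      (grid$r - 50)^2 + (grid$c - 55)^2) <= 100)
  expect_identical(sum(lab2), as.integer(oracle2))
  expect_lt(sum(lab2), 2 * sum(lab))
})

test_that("annotations reject out-of-bounds points and bad marks", {
  expect_error(point_annotation(cbind(100, 50), c(100, 100)), "outside")
  expect_error(point_annotation(cbind(-1, 50), c(100, 100)), "outside")
  expect_error(point_annotation(cbind(10, 10), c(100, 100),
                                mark_diameter = 0), "mark_diameter")
})

test_that("rasterize_marks is idempotent and order-invariant", {
  pts <- cbind(c(10, 40, 70), c(15, 60, 30))
  a1 <- rasterize_marks(point_annotation(pts, c(90, 90)))
  a2 <- rasterize_marks(point_annotation(pts[c(3, 1, 2), ], c(90, 90)))
  expect_identical(unclass(a1), unclass(a2))
  expect_identical(unclass(rasterize_marks(point_annotation(pts, c(90, 90)))),
                   unclass(a1))
})

test_that("parse_overlay_layer recovers disk centers from a red layer", {
  blank <- array(0, c(60, 80, 3))
  expect_identical(nrow(parse_overlay_layer(blank)$points), 0L)

  paint_disk <- function(ov, r0, c0, rad) {
    for (r in 0:(dim(ov)[1] - 1)) for (c in 0:(dim(ov)[2] - 1))
      if ((r - r0)^2 + (c - c0)^2 <= rad^2) {
        ov[r + 1, c + 1, 1] <- 1; ov[r + 1, c + 1, 2:3] <- 0
      }
    ov
  }
  ov <- paint_disk(blank, 30, 40, 10)
  ann <- parse_overlay_layer(ov)
  expect_identical(nrow(ann$points), 1L)
  expect_lt(max(abs(ann$points[1, ] - c(30, 40))), 0.5)

  ov2 <- paint_disk(ov, 10, 10, 5)
  expect_identical(nrow(parse_overlay_layer(ov2)$points), 2L)

  # round trip through an actual PNG file
  path <- tempfile(fileext = ".png")
  png::writePNG(ov2, path)
  expect_identical(nrow(parse_overlay_layer(path)$points), 2L)
})

test_that("derive_penalty_regions keeps only faults away from true marks", {
  ann <- point_annotation(cbind(60, 60), c(128, 128), mark_diameter = 20)
  probs <- matrix(0, 128, 128)

  # positives only inside the mark disk -> nothing penalized
  lab <- rasterize_marks(ann)
  p1 <- probs; p1[lab == 1L] <- 0.9
  expect_false(any(derive_penalty_regions(p1, ann)))

  # an isolated blob 100 px from the mark -> penalized
  p2 <- probs; p2[10:12, 10:12] <- 0.8
  pen <- derive_penalty_regions(p2, ann)
  expect_true(all(pen[10:12, 10:12]))
  expect_identical(sum(pen), 9L)

  # all-zero probabilities -> empty
  expect_false(any(derive_penalty_regions(probs, ann)))

  # sub-threshold responses are not faults
  p3 <- probs; p3[10:12, 10:12] <- 0.4
  expect_false(any(derive_penalty_regions(p3, ann, prob_threshold = 0.5)))

  expect_error(derive_penalty_regions(matrix(0, 64, 64), ann), "match")
})

test_that("weight masks hold exactly the levels {0, 1, penalty_weight}", {
  ann <- point_annotation(cbind(60, 60), c(128, 128), mark_diameter = 20)
  pen <- matrix(FALSE, 128, 128); pen[10:12, 10:12] <- TRUE

  w75 <- build_weight_mask(ann, pen, penalty_weight = 75)
  expect_identical(sum(w75 == 75), 9L)
  expect_setequal(unique(as.vector(w75)), c(0, 1, 75))

  w0 <- build_weight_mask(ann, pen, penalty_weight = 0)
  expect_true(all(w0 %in% c(0, 1)))

  plain <- build_weight_mask(point_annotation(NULL, c(64, 64)))
  expect_true(all(plain == 1))

  expect_error(build_weight_mask(ann, pen, penalty_weight = -1), ">= 0")

  # halo precedence: a penalty pixel inside the halo ring resolves to 0
  pen2 <- matrix(FALSE, 128, 128); pen2[60 + 1, 75 + 1] <- TRUE  # 15 px away
  wh <- build_weight_mask(ann, pen2, penalty_weight = 50, halo_radius = 10)
  expect_identical(wh[61, 76], 0)

  # mark disk itself keeps weight 1
  expect_identical(w75[61, 61], 1)
})

test_that("halo, penalty and mark pixels partition cleanly on random scenes", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(1:5, 1)
    pts <- cbind(runif(n, 15, 85), runif(n, 15, 85))
    ann <- point_annotation(pts, c(100, 100), mark_diameter = 12)
    lab <- rasterize_marks(ann)
    probs <- matrix(runif(100 * 100), 100, 100)
    pen <- derive_penalty_regions(probs, ann, exclusion_radius = 12,
                                  prob_threshold = 0.7)
    w <- build_weight_mask(ann, pen, penalty_weight = 50, halo_radius = 6)
    expect_true(all(w %in% c(0, 1, 50)))
    expect_false(any(pen & lab == 1L))      # penalty never on marks
    expect_false(any(w == 0 & lab == 1L))   # halo ring never on marks
    expect_true(all(w[pen] %in% c(0, 50)))  # halo precedence over penalty
  }
})

test_that("mask PNG encoding round-trips codes 0/1/2/3", {
  ann <- point_annotation(cbind(30, 30), c(64, 64), mark_diameter = 10)
  lab <- rasterize_marks(ann)
  pen <- matrix(FALSE, 64, 64); pen[5:6, 5:6] <- TRUE
  halo <- psep:::halo_mask(ann, 5)
  path <- tempfile(fileext = ".png")
  write_mask_png(lab, path, penalty = pen, halo = halo, debug = TRUE)
  codes <- read_mask_png(path)
  expect_setequal(unique(as.vector(codes)), c(0L, 1L, 2L, 3L))
  expect_identical(codes == 1L, unclass(lab) == 1L)
  expect_identical(which(codes == 2L), which(pen))
  expect_identical(codes == 3L, halo & !(lab == 1L))
})
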