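# Minimal raster painting helpers (0-based pixel-center coordinates).
# Used by the synthetic scene generator and the match visualizations.

clip_rc <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# paint a filled disk; color length-3 in [0,1]; alpha blends over the image
draw_disk <- function(img, center, radius, color, alpha = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r0 <- floor(center[1] - radius); r1 <- ceiling(center[1] + radius)
  c0 <- floor(center[2] - radius); c1 <- ceiling(center[2] + radius)
  rr <- clip_rc(r0, 0, h - 1):clip_rc(r1, 0, h - 1)
  cc <- clip_rc(c0, 0, w - 1):clip_rc(c1, 0, w - 1)
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, `+`)
  inside <- d2 <= radius^2
  if (!any(inside)) return(img)
  for (ch in 1:3) {
    sub <- img[rr + 1, cc + 1, ch]
    sub[inside] <- (1 - alpha) * sub[inside] + alpha * color[ch]
    img[rr + 1, cc + 1, ch] <- sub
  }
  img
}

# paint a line segment of given stroke width (pixels)
draw_segment <- function(img, p0, p1, color, width = 1, alpha = 1) {
  h <- dim(img)[1]; w <- dim(img)[2]
  hw <- width / 2
  r0 <- floor(min(p0[1], p1[1]) - hw); r1 <- ceiling(max(p0[1], p1[1]) + hw)
  c0 <- floor(min(p0[2], p1[2]) - hw); c1 <- ceiling(max(p0[2], p1[2]) + hw)
  rr <- clip_rc(r0, 0, h - 1):clip_rc(r1, 0, h - 1)
  cc <- clip_rc(c0, 0, w - 1):clip_rc(c1, 0, w - 1)
  py <- matrix(rr, length(rr), length(cc))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  vy <- p1[1] - p0[1]; vx <- p1[2] - p0[2]
  len2 <- vy^2 + vx^2
  if (len2 == 0) return(draw_disk(img, p0, hw, color, alpha))
  t <- ((py - p0[1]) * vy + (px - p0[2]) * vx) / len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (py - (p0[1] + t * vy))^2 + (px - (p0[2] + t * vx))^2
  inside <- d2 <= hw^2
  if (!any(inside)) return(img)
  for (ch in 1:3) {
    sub <- img[rr + 1, cc + 1, ch]
    sub[inside] <- (1 - alpha) * sub[inside] + alpha * color[ch]
    img[rr + 1, cc + 1, ch] <- sub
  }
  img
}

# tapered curved stroke: a quadratic bezier from `base` towards `tip` bent by
# `bend`, drawn as short segments whose width shrinks from width0 to width1
draw_leaf_stroke <- function(img, base, tip, bend, color,
                             width0 = 2.5, width1 = 1, n_seg = 8) {
  ctrl <- (base + tip) / 2 + bend
  ts <- seq(0, 1, length.out = n_seg + 1)
  pts <- sapply(ts, function(t)
    (1 - t)^2 * base + 2 * t * (1 - t) * ctrl + t^2 * tip)
  for (i in seq_len(n_seg)) {
    wdt <- width0 + (width1 - width0) * (i - 0.5) / n_seg
    img <- draw_segment(img, pts[, i], pts[, i + 1], color, width = wdt)
  }
  img
}
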