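# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_shape2 <- function(a, b, what_a, what_b) {
  da <- dim(a)[1:2]
  db <- dim(b)[1:2]
  if (!identical(as.integer(da), as.integer(db)))
    stopf("%s (%dx%d) and %s (%dx%d) must share the same height and width",
          what_a, da[1], da[2], what_b, db[1], db[2])
  invisible(TRUE)
}

# Squared Euclidean distance from every pixel center to the nearest of a set
# of (row, col) points (0-based). Returns an H x W matrix; Inf when no points.
# Exact by brute force per point, restricted to a bounding box when `within`
# (a radius) is given, in which case distances beyond `within` may be reported
# as Inf.
nearest_point_dist2 <- function(points, shape, within = NULL) {
  h <- shape[1]; w <- shape[2]
  d2 <- matrix(Inf, h, w)
  if (length(points) == 0 || NROW(points) == 0) return(d2)
  pts <- as.matrix(points)
  rows0 <- 0:(h - 1)
  cols0 <- 0:(w - 1)
  for (i in seq_len(nrow(pts))) {
    pr <- pts[i, 1]; pc <- pts[i, 2]
    if (is.null(within)) {
      rr <- seq_len(h); cc <- seq_len(w)
    } else {
      rr <- which(abs(rows0 - pr) <= within)
      cc <- which(abs(cols0 - pc) <= within)
      if (!length(rr) || !length(cc)) next
    }
    dd <- outer((rows0[rr] - pr)^2, (cols0[cc] - pc)^2, `+`)
    d2[rr, cc] <- pmin(d2[rr, cc], dd)
  }
  d2
}
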