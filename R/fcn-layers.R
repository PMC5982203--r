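# Low-level array operations for the fully-convolutional network.
#
# All activations are H x W x C double arrays (single image). Convolutions are
# implemented as im2col patch gathers followed by one BLAS matrix multiply;
# patch columns are ordered (dy, dx, channel) with channel fastest, matching
# the row order of the kernel matrix. The backward passes are exact adjoints.

# zero-pad an H x W x C array by p on every side
pad_zero3 <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

# replicate-pad bottom/right so both spatial dims become multiples of m
pad_to_multiple <- function(x, m) {
  d <- dim(x)
  hb <- (m - d[1] %% m) %% m
  wb <- (m - d[2] %% m) %% m
  if (hb == 0 && wb == 0) return(x)
  ri <- c(seq_len(d[1]), rep(d[1], hb))
  ci <- c(seq_len(d[2]), rep(d[2], wb))
  x[ri, ci, , drop = FALSE]
}

im2col <- function(xp, h, w, k, cin) {
  n <- h * w
  P <- matrix(0, n, k * k * cin)
  blk <- 0L
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    P[, (blk * cin + 1):((blk + 1) * cin)] <-
      xp[dy + seq_len(h), dx + seq_len(w), ]
    blk <- blk + 1L
  }
  P
}

col2im <- function(dP, h, w, k, cin, p) {
  dxp <- array(0, c(h + 2 * p, w + 2 * p, cin))
  blk <- 0L
  for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
    sl <- dP[, (blk * cin + 1):((blk + 1) * cin)]
    dim(sl) <- c(h, w, cin)
    dxp[dy + seq_len(h), dx + seq_len(w), ] <-
      dxp[dy + seq_len(h), dx + seq_len(w), ] + sl
    blk <- blk + 1L
  }
  dxp[(p + 1):(p + h), (p + 1):(p + w), , drop = FALSE]
}

# conv: W is a (k*k*cin) x cout matrix, b length cout; 'same' padding
conv_fwd <- function(x, W, b, k, training = FALSE) {
  d <- dim(x)
  cin <- d[3]; cout <- length(b)
  if (k == 1) {
    P <- x; dim(P) <- c(d[1] * d[2], cin)
  } else {
    p <- (k - 1) %/% 2
    P <- im2col(pad_zero3(x, p), d[1], d[2], k, cin)
  }
  out <- P %*% W
  out <- sweep(out, 2, b, `+`)
  dim(out) <- c(d[1], d[2], cout)
  if (training) list(out = out, P = P, xdim = d) else list(out = out)
}

conv_bwd <- function(dout, cache, W, k, need_dx = TRUE) {
  d <- cache$xdim
  cout <- ncol(W)
  dO <- dout; dim(dO) <- c(d[1] * d[2], cout)
  dW <- crossprod(cache$P, dO)
  db <- colSums(dO)
  dx <- NULL
  if (need_dx) {
    dP <- dO %*% t(W)
    if (k == 1) {
      dx <- dP; dim(dx) <- d
    } else {
      p <- (k - 1) %/% 2
      dx <- col2im(dP, d[1], d[2], k, d[3], p)
    }
  }
  list(dW = dW, db = db, dx = dx)
}

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

relu_bwd <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

# 2x2 max pooling, stride 2 (spatial dims must be even)
maxpool_fwd <- function(x, training = FALSE) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  oi <- seq(1, d[1], 2); ei <- oi + 1
  oj <- seq(1, d[2], 2); ej <- oj + 1
  n <- h2 * w2 * d[3]
  M <- matrix(0, n, 4)
  M[, 1] <- x[oi, oj, ]
  M[, 2] <- x[ei, oj, ]
  M[, 3] <- x[oi, ej, ]
  M[, 4] <- x[ei, ej, ]
  amax <- max.col(M, ties.method = "first")
  out <- M[cbind(seq_len(n), amax)]
  dim(out) <- c(h2, w2, d[3])
  if (!training) return(list(out = out))
  list(out = out, amax = amax, xdim = d)
}

maxpool_bwd <- function(dout, cache) {
  d <- cache$xdim
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  # linear index of the argmax inside the original array
  cell <- seq_len(h2 * w2 * d[3]) - 1L
  i2 <- cell %% h2
  j2 <- (cell %/% h2) %% w2
  cc <- cell %/% (h2 * w2)
  dr <- c(0L, 1L, 0L, 1L)[cache$amax]
  dc <- c(0L, 0L, 1L, 1L)[cache$amax]
  lin <- (2L * i2 + dr) + d[1] * (2L * j2 + dc) + d[1] * d[2] * cc + 1L
  dx <- array(0, d)
  dx[lin] <- dout
  dx
}

# nearest-neighbour 2x upsampling
upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(dout) {
  d <- dim(dout)
  oi <- seq(1, d[1], 2); ei <- oi + 1
  oj <- seq(1, d[2], 2); ej <- oj + 1
  dout[oi, oj, , drop = FALSE] + dout[ei, oj, , drop = FALSE] +
    dout[oi, ej, , drop = FALSE] + dout[ei, ej, , drop = FALSE]
}

# numerically-stable two-class softmax over the channel dimension
softmax2 <- function(z) {
  m <- pmax(z[, , 1], z[, , 2])
  e1 <- exp(z[, , 1] - m)
  e2 <- exp(z[, , 2] - m)
  s <- e1 + e2
  out <- array(0, dim(z))
  out[, , 1] <- e1 / s
  out[, , 2] <- e2 / s
  out
}
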