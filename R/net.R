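## Minimal convolutional-network engine used by the DOPU synthesis module.
## Internal tensors are 4-d arrays [H, W, N, C] (channel-last, so im2col
## slices are already in matrix order and no transposes are needed).
## Convolutions are 3x3, stride 1, zero-padded, computed by im2col so the
## inner product runs on BLAS.

.pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  out[2:(d[1L] + 1L), 2:(d[2L] + 1L), , ] <- x
  out
}

# im2col for a padded input: contiguous column blocks, one per kernel
# offset (ki fastest, then kj), each holding all input channels.
.im2col <- function(xp, H, W, N, Cin) {
  X <- matrix(0, H * W * N, 9L * Cin)
  for (kj in 0:2) for (ki in 0:2) {
    o <- ki + 3L * kj
    X[, o * Cin + seq_len(Cin)] <-
      xp[ki + seq_len(H), kj + seq_len(W), , , drop = FALSE]
  }
  X
}

# Weight array [3, 3, Cin, Cout] -> matrix with rows ordered to match the
# im2col column order (cin fastest within each offset block).
.wmat <- function(w) {
  d <- dim(w)
  matrix(aperm(w, c(3L, 1L, 2L, 4L)), 9L * d[3L], d[4L])
}

# Plain convolution y = x * w + b without caching (used for the forward
# pass of the gradient's transposed convolution too).
.conv_raw <- function(x, w, b = NULL) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; N <- d[3L]; Cin <- d[4L]
  X <- .im2col(.pad1(x), H, W, N, Cin)
  Y <- X %*% .wmat(w)
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  list(y = array(Y, c(H, W, N, dim(w)[4L])), X = X)
}

conv_fwd <- function(x, w, b) {
  r <- .conv_raw(x, w, b)
  list(y = r$y, X = r$X, dim_in = dim(x))
}

conv_bwd <- function(cache, w, dy) {
  d <- cache$dim_in; H <- d[1L]; W <- d[2L]; N <- d[3L]; Cin <- d[4L]
  Cout <- dim(w)[4L]
  dY <- matrix(dy, H * W * N, Cout)
  dwm <- crossprod(cache$X, dY)                    # rows: (cin, ki, kj)
  dw <- aperm(array(dwm, c(Cin, 3L, 3L, Cout)), c(2L, 3L, 1L, 4L))
  db <- colSums(dY)
  # dX is the correlation of dY with the spatially flipped, transposed kernel
  wt <- aperm(w[3:1, 3:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
  dx <- .conv_raw(dy, wt)$y
  list(dx = dx, dw = dw, db = db)
}

relu_fwd <- function(x) {
  y <- x; y[y < 0] <- 0
  list(y = y, mask = x > 0)
}
relu_bwd <- function(cache, dy) dy * cache$mask

# 2x2 average pooling (stride 2); exact, smooth backward pass.
pool_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2L], 2L); j2 <- j1 + 1L
  (x[i1, j1, , , drop = FALSE] + x[i2, j1, , , drop = FALSE] +
     x[i1, j2, , , drop = FALSE] + x[i2, j2, , , drop = FALSE]) / 4
}
pool_bwd <- function(dy, dim_in) {
  dx <- array(0, dim_in)
  i1 <- seq(1L, dim_in[1L], 2L); j1 <- seq(1L, dim_in[2L], 2L)
  g <- dy / 4
  dx[i1, j1, , ] <- g; dx[i1 + 1L, j1, , ] <- g
  dx[i1, j1 + 1L, , ] <- g; dx[i1 + 1L, j1 + 1L, , ] <- g
  dx
}

# Nearest-neighbour x2 upsampling.
upsample_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1L], 2L * d[2L], d[3L], d[4L]))
  i1 <- seq(1L, 2L * d[1L], 2L); j1 <- seq(1L, 2L * d[2L], 2L)
  y[i1, j1, , ] <- x; y[i1 + 1L, j1, , ] <- x
  y[i1, j1 + 1L, , ] <- x; y[i1 + 1L, j1 + 1L, , ] <- x
  y
}
upsample_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1L], 2L); j1 <- seq(1L, d[2L], 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i1 + 1L, j1, , , drop = FALSE] +
    dy[i1, j1 + 1L, , , drop = FALSE] + dy[i1 + 1L, j1 + 1L, , , drop = FALSE]
}

# Concatenate along the channel (4th) dimension.
concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L], da[4L] + db[4L]))
  out[, , , seq_len(da[4L])] <- a
  out[, , , da[4L] + seq_len(db[4L])] <- b
  out
}

# He-initialized 3x3 conv parameters.
.init_conv <- function(cin, cout) {
  list(w = array(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                 c(3L, 3L, cin, cout)),
       b = rep(0, cout))
}

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(p = p - lr * mh / (sqrt(vh) + eps), state = state)
}
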