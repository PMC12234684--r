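#' @keywords internal
"_PACKAGE"

## Shared array/index conventions
## ------------------------------
## Volumes are stored as arrays indexed [depth, aline, bscan] (1-based, depth
## index 1 on the vitreous side, increasing toward the choroid). En-face maps
## are [aline, bscan]. Raw tomogram fields add channel and repeat as trailing
## dimensions: [depth, aline, bscan, channel, repeat] with channel 1 = H,
## channel 2 = V. Every module in the package shares these conventions.

# Summed-area table of a (possibly complex) matrix, with a leading zero
# row/column so window sums reduce to four lookups.
.sat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # double cumulative sum as triangular matrix products (runs on BLAS)
  L <- matrix(0, nr, nr); L[lower.tri(L, diag = TRUE)] <- 1
  U <- matrix(0, nc, nc); U[upper.tri(U, diag = TRUE)] <- 1
  out <- matrix(if (is.complex(m)) 0i else 0, nr + 1L, nc + 1L)
  out[-1L, -1L] <- L %*% m %*% U
  out
}

# Index matrices (clipped window bounds) for a truncated box window.
.box_bounds <- function(nr, nc, k) {
  hr <- (k[1L] - 1L) %/% 2L
  hc <- (k[2L] - 1L) %/% 2L
  r1 <- pmax(seq_len(nr) - hr, 1L); r2 <- pmin(seq_len(nr) + hr, nr)
  c1 <- pmax(seq_len(nc) - hc, 1L); c2 <- pmin(seq_len(nc) + hc, nc)
  list(r1 = r1, r2 = r2, c1 = c1, c2 = c2)
}

# Moving box sum over a matrix with windows truncated at the borders
# (no padding: edge windows average over the voxels that exist).
box_sum <- function(m, k = c(3L, 3L)) {
  stopifnot(length(k) == 2L, all(k >= 1L), all(k %% 2L == 1L))
  nr <- nrow(m); nc <- ncol(m)
  S <- .sat(m)
  b <- .box_bounds(nr, nc, k)
  R1 <- matrix(b$r1, nr, nc); R2 <- matrix(b$r2, nr, nc)
  C1 <- matrix(b$c1, nr, nc, byrow = TRUE); C2 <- matrix(b$c2, nr, nc, byrow = TRUE)
  idx <- function(r, c) S[cbind(as.vector(r), as.vector(c))]
  v <- idx(R2 + 1L, C2 + 1L) - idx(R1, C2 + 1L) - idx(R2 + 1L, C1) + idx(R1, C1)
  matrix(v, nr, nc)
}

# Number of in-bounds voxels in each truncated window.
box_count <- function(nr, nc, k = c(3L, 3L)) {
  b <- .box_bounds(nr, nc, k)
  outer(b$r2 - b$r1 + 1L, b$c2 - b$c1 + 1L)
}

# Cumulative sum along the depth (first) dimension of a [depth, aline, bscan]
# array, kept as a matrix op for speed.
cumsum_depth <- function(a) {
  d <- dim(a)
  m <- matrix(a, d[1L], prod(d[-1L]))
  cs <- apply(m, 2L, cumsum)
  array(cs, d)
}

# Complex circular Gaussian array with per-element power (variance) `pow`;
# `pow` may be a scalar combined with an explicit length `n`.
.cgauss <- function(pow, n = length(pow)) {
  amp <- sqrt(as.vector(pow) / 2)
  z <- complex(real = stats::rnorm(n) * amp, imaginary = stats::rnorm(n) * amp)
  if (!is.null(dim(pow))) array(z, dim(pow)) else z
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable short hash of an R object (used to stamp derived outputs with the
# configuration that produced them).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
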