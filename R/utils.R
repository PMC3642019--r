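# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
# Out-of-range positions return `fill`.
bilinear <- function(m, r, c, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & r0 <= nr & c0 >= 1 & c0 <= nc
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  out <- rep(fill, length(r))
  if (!any(ok)) return(out)
  i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r1[ok], c0[ok])
  i01 <- cbind(r0[ok], c1[ok]); i11 <- cbind(r1[ok], c1[ok])
  fr <- fr[ok]; fc <- fc[ok]
  out[ok] <- m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
  out
}

# Linear-interpolated sampling of vector `v` at fractional positions `x`
# (1-based); outside the support returns `fill`.
interp1 <- function(v, x, fill = 0) {
  n <- length(v)
  i0 <- floor(x)
  f <- x - i0
  ok <- i0 >= 1 & x <= n
  i1 <- pmin(i0 + 1, n)
  out <- rep(fill, length(x))
  if (any(ok)) out[ok] <- v[i0[ok]] * (1 - f[ok]) + v[i1[ok]] * f[ok]
  out
}

# Shift the columns of a matrix by a fractional number of columns
# (positive = content moves toward higher column index), linear interpolation.
shift_cols <- function(m, shift, fill = 0) {
  if (shift == 0) return(m)
  nc <- ncol(m)
  pos <- seq_len(nc) - shift
  t(apply(m, 1L, interp1, x = pos, fill = fill))
}

# 5-point discrete Laplacian with replicate (edge-clamped) padding.
laplacian5 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up    <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + down + left + right - 4 * m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable Gaussian blur with edge-replicated padding.
gauss_blur <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    padded <- c(rep(v[1], rad), v, rep(v[length(v)], rad))
    stats::filter(padded, k, sides = 2)[(rad + 1):(rad + length(v))]
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(m2, 1L, conv1))
}
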