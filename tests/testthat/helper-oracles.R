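# Shared fixtures and independent oracles, all built in code.

# Vertical cylinder (tube) phantom centred in an n x n x nz grid.
cylinder_phantom <- function(n = 128L, nz = 2L, radius_um = 180,
                             voxel_um = 9, contrast_per_um = 0.007) {
  ctr_px <- n / 2 + 0.5  # voxel-centre aligned
  tree <- parallel_tube_tree(matrix(c(ctr_px, ctr_px), 1), radius_um, nz,
                             voxel_um, contrast_per_um)
  suppressWarnings(voxelize(tree, voxel_um, dim = c(n, n, nz)))
}

# Smooth asymmetric phantom: a few Gaussian blobs (bilinear sampling of a
# smooth field keeps discretization error low).
blob_phantom <- function(n = 64L, nz = 1L,
                         blobs = list(c(24, 30, 5, 0.004),
                                      c(40, 38, 7, 0.006))) {
  g <- array(0, c(n, n, nz))
  xs <- seq_len(n)
  sl <- matrix(0, n, n)
  for (b in blobs) {
    d2 <- outer((xs - b[1])^2, (xs - b[2])^2, "+")
    sl <- sl + b[4] * exp(-d2 / (2 * b[3]^2))
  }
  for (k in seq_len(nz)) g[, , k] <- sl
  structure(list(grid = g, voxel_size_um = 9, origin = c(0, 0, 0),
                 log = character()), class = "voxel_phantom")
}

# Analytic parallel-ray log-projection of a centred cylinder:
# 2 * mu * sqrt(R^2 - x^2).
chord_profile <- function(n, radius_um, voxel_um = 9, contrast_per_um = 0.007) {
  x <- (seq_len(n) - (n + 1) / 2) * voxel_um
  ifelse(abs(x) < radius_um,
         2 * contrast_per_um * sqrt(pmax(radius_um^2 - x^2, 0)), 0)
}

# Independent brute-force FBP: filter built from the textbook band-limited
# ramp kernel, back-projection as an explicit per-pixel loop with approx().
brute_force_fbp <- function(sino_data, angles_deg, filter_name = "ramlak") {
  n <- ncol(sino_data)
  n_ang <- nrow(sino_data)
  size <- max(64L, 2L^ceiling(log2(2L * n)))
  # real-space Ram-Lak kernel h(0)=1/4, h(odd k)=-1/(pi k)^2, h(even)=0
  idx <- c(0:(size %/% 2), -((size %/% 2 - 1):1))
  h <- ifelse(idx == 0, 0.25,
              ifelse(idx %% 2 != 0, -1 / (pi * idx)^2, 0))
  filt <- 2 * Re(stats::fft(h))
  freq <- idx / size
  if (filter_name == "shepp-logan")
    filt <- filt * ifelse(freq == 0, 1, sin(pi * freq) / (pi * freq))
  if (filter_name == "hann")
    filt <- filt * 0.5 * (1 + cos(2 * pi * freq))
  filtered <- matrix(0, n_ang, n)
  for (a in seq_len(n_ang)) {
    row <- c(sino_data[a, ], numeric(size - n))
    filtered[a, ] <- Re(stats::fft(stats::fft(row) * filt,
                                   inverse = TRUE))[seq_len(n)] / size
  }
  c0 <- (n + 1) / 2
  out <- matrix(0, n, n)
  th <- angles_deg * pi / 180
  for (x in seq_len(n)) {
    for (y in seq_len(n)) {
      acc <- 0
      for (a in seq_len(n_ang)) {
        t <- (x - c0) * cos(th[a]) + (y - c0) * sin(th[a]) + c0
        if (t >= 1 && t <= n)
          acc <- acc + stats::approx(seq_len(n), filtered[a, ], t)$y
      }
      out[x, y] <- acc
    }
  }
  out * pi / (2 * n_ang)
}

# Shift every sinogram row by `shift` columns (linear interpolation),
# emulating a detector whose centre is offset from the rotation axis.
shift_sinogram <- function(sino, shift) {
  n <- ncol(sino$data)
  sino$data <- t(apply(sino$data, 1, function(r)
    stats::approx(seq_len(n), r, seq_len(n) - shift, yleft = 0,
                  yright = 0)$y))
  sino
}

# Exhaustive-search Otsu oracle working on the raw sample (not histogram):
# evaluates the between-class variance at each of 256 candidate cuts.
otsu_oracle <- function(v, nbins = 256L) {
  rng <- range(v)
  cands <- seq(rng[1], rng[2], length.out = nbins + 1L)[2:nbins]
  bcv <- vapply(cands, function(t) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cands[which.max(bcv)]
}

# Rectangular tube image (vertical band of width d px with partial-volume
# edges), optionally blurred and noised: fixture for diameter recovery.
tube_band_image <- function(d_px, n = 64L, centre = NULL, blur_sigma = 0.7,
                            depth = 0.3, noise_sd = 0, seed = NULL) {
  if (is.null(centre)) centre <- n / 2 + 0.37
  cols <- seq_len(n)
  cover <- pmax(0, pmin(cols + 0.5, centre + d_px / 2) -
                  pmax(cols - 0.5, centre - d_px / 2))
  profile <- 1 - depth * cover
  img <- matrix(rep(profile, each = n), n, n)
  if (blur_sigma > 0) img <- vesselct:::gauss_blur(img, blur_sigma)
  if (noise_sd > 0) {
    img <- vesselct:::with_seed(seed, img + matrix(rnorm(n * n, 0, noise_sd), n, n))
  }
  img
}
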