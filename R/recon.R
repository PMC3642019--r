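#' Flat-field normalization of projections
#'
#' Converts raw intensity projections to log-attenuation,
#' `-log(I / I0)`, where `I0` is the mean of the pre- and post-scan
#' background frames. Non-positive intensities (possible under read noise or
#' strong edge enhancement) are replaced by the smallest positive value in
#' their 3 x 3 neighbourhood before the log; the number of such repairs is
#' recorded in the result's `log`.
#'
#' @param pset A `projection_set` in the intensity domain.
#' @param floor Lower clip for the attenuation values (default 0); `NULL`
#'   disables clipping.
#' @return A `projection_set` with `domain = "attenuation"`.
#' @export
normalize_projections <- function(pset, floor = 0) {
  stopifnot(inherits(pset, "projection_set"))
  if (identical(pset$domain, "attenuation"))
    stop("projections already normalized")
  bg <- pset$background
  I0 <- if (is.list(bg)) (bg[[1]] + bg[[2]]) / 2 else bg
  if (any(I0 <= 0)) stop("background flat field must be strictly positive")
  n_repaired <- 0L
  images <- lapply(pset$images, function(I) {
    bad <- which(I <= 0)
    if (length(bad)) {
      n_repaired <<- n_repaired + length(bad)
      I <- repair_nonpositive(I, bad)
    }
    att <- -log(I / I0)
    if (!is.null(floor)) att <- pmax(att, floor)
    att
  })
  out <- pset
  out$images <- images
  out$domain <- "attenuation"
  out$log <- c(pset$log,
               if (n_repaired) sprintf("%d non-positive pixels repaired", n_repaired))
  out
}

# Replace non-positive pixels by the smallest positive 3x3-neighbour value
# (global smallest positive as a last resort).
repair_nonpositive <- function(I, bad) {
  nr <- nrow(I); nc <- ncol(I)
  gmin <- min(I[I > 0], na.rm = TRUE)
  if (!is.finite(gmin)) stop("projection contains no positive intensities")
  for (b in bad) {
    r <- (b - 1L) %% nr + 1L; c <- (b - 1L) %/% nr + 1L
    nb <- I[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
    nb <- nb[nb > 0]
    I[b] <- if (length(nb)) min(nb) else gmin
  }
  I
}

#' Assemble the sinogram of one detector row
#'
#' Stacks row `slice_row` of every normalized projection, ordered by angle,
#' into the angles-by-columns sinogram that feeds per-slice reconstruction.
#'
#' @param pset A normalized `projection_set` (attenuation domain).
#' @param slice_row Detector row (1-based).
#' @return A `sinogram`: list with `data` (n_angles x n_cols matrix),
#'   `angles_deg`, `axis_offset` (fractional columns, initially 0) and
#'   `slice_row`.
#' @export
assemble_sinogram <- function(pset, slice_row) {
  stopifnot(inherits(pset, "projection_set"))
  if (!identical(pset$domain, "attenuation"))
    warning("assembling a sinogram from un-normalized intensity projections")
  nr <- nrow(pset$images[[1]])
  if (slice_row < 1 || slice_row > nr)
    stop(sprintf("slice_row %d outside detector rows 1..%d", slice_row, nr))
  data <- t(vapply(pset$images, function(I) I[slice_row, ],
                   numeric(ncol(pset$images[[1]]))))
  if (!all(is.finite(data))) stop("sinogram contains non-finite values")
  structure(list(data = data, angles_deg = pset$angles_deg, axis_offset = 0,
                 slice_row = slice_row),
            class = "sinogram")
}

#' Estimate the rotation-axis offset of a sinogram
#'
#' A parallel-beam projection at 180 degrees is the mirror image of the
#' 0-degree projection about the rotation-axis column. The offset of that
#' column from the detector centre is found by mirroring the
#' largest-available-angle row about candidate axis positions on a
#' 0.1-column grid and minimizing the L2 distance to the 0-degree row.
#' (With projections at 0..179 degrees the 179-degree row stands in for the
#' missing 180-degree frame.)
#'
#' @param sino A `sinogram`.
#' @param max_shift Search half-range in columns (default 20).
#' @return The axis offset in fractional detector columns (positive = axis
#'   right of centre).
#' @export
estimate_axis <- function(sino, max_shift = 20) {
  stopifnot(inherits(sino, "sinogram"))
  p0 <- sino$data[1L, ]
  pm <- sino$data[nrow(sino$data), ]
  if (all(p0 == 0) || all(pm == 0)) stop("no signal for axis estimation")
  n <- length(p0)
  c0 <- (n + 1) / 2
  x <- seq_len(n)
  deltas <- seq(-max_shift, max_shift, by = 0.1)
  cost <- vapply(deltas, function(d) {
    mirrored <- interp1(pm, 2 * (c0 + d) - x, fill = 0)
    sum((p0 - mirrored)^2)
  }, numeric(1))
  deltas[which.min(cost)]
}

# Frequency response of the reconstruction filter on a length-`size` FFT
# grid. The ramp (Ram-Lak) filter is built from its exact band-limited
# real-space kernel to avoid the DC bias of a naive |f| ramp.
fbp_filter <- function(size, filter_name) {
  filters <- c("ramlak", "shepp-logan", "hann")
  if (!filter_name %in% filters)
    stop(sprintf("unknown filter '%s'; options: %s", filter_name,
                 paste(filters, collapse = ", ")))
  h <- numeric(size)
  h[1] <- 0.25
  k <- seq_len(size %/% 2)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi * odd)^2
  h[size + 1 - odd] <- -1 / (pi * odd)^2
  f <- 2 * Re(stats::fft(h))
  freq <- c(seq(0, size %/% 2 - 1), seq(-(size %/% 2), -1)) / size  # cycles/sample
  if (filter_name == "shepp-logan") {
    sinc <- ifelse(freq == 0, 1, sin(pi * freq) / (pi * freq))
    f <- f * sinc
  } else if (filter_name == "hann") {
    f <- f * 0.5 * (1 + cos(2 * pi * freq))
  }
  f
}

#' Filtered back-projection of a sinogram
#'
#' Standard parallel-beam FBP: the sinogram is shifted by the stored
#' rotation-axis offset (linear interpolation), each angular row is
#' ramp-filtered in the frequency domain (Ram-Lak by default, optionally
#' Shepp-Logan or Hann apodized), and the filtered rows are back-projected
#' with linear interpolation. The output is a square slice with side equal
#' to the detector column count, in the same per-pixel attenuation units as
#' the phantom's [attenuation_slice()]. Values outside the support are left
#' as reconstructed (possibly negative): clipping before segmentation would
#' bias the Otsu threshold.
#'
#' @param sino A `sinogram` (its `axis_offset` is honoured).
#' @param filter_name `"ramlak"` (default), `"shepp-logan"` or `"hann"`.
#' @return An n x n matrix.
#' @export
fbp <- function(sino, filter_name = "ramlak") {
  stopifnot(inherits(sino, "sinogram"))
  data <- sino$data
  if (!is.null(sino$axis_offset) && sino$axis_offset != 0)
    data <- shift_cols(data, -sino$axis_offset, fill = 0)
  n <- ncol(data)
  n_ang <- nrow(data)
  size <- max(64L, 2L^ceiling(log2(2L * n)))
  filt <- fbp_filter(size, filter_name)
  filtered <- matrix(0, n_ang, n)
  for (a in seq_len(n_ang)) {
    row <- c(data[a, ], numeric(size - n))
    fr <- Re(stats::fft(stats::fft(row) * filt, inverse = TRUE)) / size
    filtered[a, ] <- fr[seq_len(n)]
  }
  c0 <- (n + 1) / 2
  xs <- matrix(seq_len(n) - c0, n, n)        # rows: x
  ys <- matrix(seq_len(n) - c0, n, n, byrow = TRUE)
  recon <- matrix(0, n, n)
  th <- sino$angles_deg * pi / 180
  for (a in seq_len(n_ang)) {
    t <- xs * cos(th[a]) + ys * sin(th[a]) + c0
    recon <- recon + matrix(interp1(filtered[a, ], as.numeric(t), fill = 0), n, n)
  }
  recon * pi / (2 * n_ang)
}

#' Equalize the background gray level of a reconstructed slice
#'
#' Sample thickness varies along the vertical axis, so the reconstructed
#' background gray level drifts between slices. This sets a common mid-gray:
#' the background level is estimated as the histogram mode (256 bins) inside
#' a central annulus assumed to lie outside the vessel support, and the
#' slice is shifted so that level maps to `target`.
#'
#' @param slice Reconstructed 2D slice.
#' @param target Gray value the background is mapped to (default 0.5).
#' @param annulus Inner/outer annulus radii as fractions of the half-width
#'   (default `c(0.55, 0.85)`).
#' @return The shifted slice, with attributes `background_gray` (= `target`)
#'   and `background_mode` (the estimated level).
#' @export
equalize_background <- function(slice, target = 0.5, annulus = c(0.55, 0.85)) {
  stopifnot(all(is.finite(slice)), length(annulus) == 2L,
            annulus[1] < annulus[2])
  n <- nrow(slice); m <- ncol(slice)
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  r <- sqrt(outer((seq_len(n) - cx)^2, (seq_len(m) - cy)^2, "+"))
  half <- min(n, m) / 2
  ring <- slice[r >= annulus[1] * half & r <= annulus[2] * half]
  rng <- range(ring)
  if (diff(rng) == 0) {
    warning("degenerate histogram: constant background; slice unchanged")
    out <- slice
    attr(out, "background_gray") <- NA_real_
    attr(out, "background_mode") <- rng[1]
    return(out)
  }
  h <- graphics::hist(ring, breaks = seq(rng[1], rng[2], length.out = 257),
                      plot = FALSE)
  mode_val <- h$mids[which.max(h$counts)]
  out <- slice - mode_val + target
  attr(out, "background_gray") <- target
  attr(out, "background_mode") <- mode_val
  out
}

#' Reconstruct a volume of slices from a projection set
#'
#' Runs the full per-slice chain: flat-field normalization, sinogram
#' assembly, one rotation-axis estimation (on the detector row with the most
#' signal), filtered back-projection of each requested row, and background
#' gray-value equalization.
#'
#' @param pset A `projection_set` (intensity domain).
#' @param rows Detector rows to reconstruct (default all).
#' @param filter_name FBP filter (see [fbp()]).
#' @param equalize Apply [equalize_background()] per slice (default TRUE).
#' @param target Background gray target passed to [equalize_background()].
#' @return A `slice_volume`: list with `slices` (list of matrices), `rows`,
#'   `voxel_size_um`, `axis_offset`, `filter`, `background_gray`,
#'   `provenance` and per-slice `timings_s`.
#' @export
reconstruct_volume <- function(pset, rows = NULL, filter_name = "ramlak",
                               equalize = TRUE, target = 0.5) {
  stopifnot(inherits(pset, "projection_set"))
  norm <- normalize_projections(pset)
  nr <- nrow(norm$images[[1]])
  if (is.null(rows)) rows <- seq_len(nr)
  stopifnot(all(rows >= 1), all(rows <= nr))
  signal_per_row <- Reduce(`+`, lapply(norm$images, rowSums))
  axis_row <- which.max(signal_per_row)
  axis_offset <- if (signal_per_row[axis_row] > 0) {
    estimate_axis(assemble_sinogram(norm, axis_row))
  } else 0
  slices <- vector("list", length(rows))
  timings <- numeric(length(rows))
  for (i in seq_along(rows)) {
    t0 <- proc.time()[["elapsed"]]
    sino <- assemble_sinogram(norm, rows[i])
    sino$axis_offset <- axis_offset
    sl <- fbp(sino, filter_name)
    if (equalize) sl <- equalize_background(sl, target = target)
    slices[[i]] <- sl
    timings[i] <- proc.time()[["elapsed"]] - t0
  }
  structure(list(slices = slices, rows = rows,
                 voxel_size_um = pset$pixel_pitch_um,
                 axis_offset = axis_offset, filter = filter_name,
                 background_gray = if (equalize) target else NA_real_,
                 provenance = pset$group_id %||% "projection_set",
                 timings_s = timings),
            class = "slice_volume")
}

#' @export
print.slice_volume <- function(x, ...) {
  cat(sprintf("slice_volume: %d slices of %d x %d at %g um (%s filter, axis offset %.2f)\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$voxel_size_um, x$filter, x$axis_offset))
  invisible(x)
}
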