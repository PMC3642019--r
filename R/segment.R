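#' Otsu's threshold on a 256-bin histogram
#'
#' Computes the global gray-level threshold maximizing the between-class
#' variance over a 256-bin histogram spanning the image's own min-max
#' range. Candidate thresholds are the interior bin edges; the returned
#' value is the edge achieving the maximum (midpoint of the optimal edges
#' when several tie).
#'
#' @param image Numeric matrix (or vector) of gray values.
#' @param nbins Number of histogram bins (default 256).
#' @return The scalar threshold.
#' @export
otsu_threshold <- function(image, nbins = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct values")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins),
                     nbins = nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  n <- w[nbins]; mt <- m[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mt * w0[valid] - n * m[-nbins][valid])^2 /
    (w0[valid] * w1[valid])
  best <- which(bcv == max(bcv))
  # threshold at the bin edge; average over ties
  mean(edges[best + 1L])
}

#' Define a region-of-interest grid
#'
#' The scoring ROI: a square window partitioned into equal square blocks.
#' The default is the standard 200 x 200-pixel window divided into 25
#' blocks of 40 x 40 pixels.
#'
#' @param origin `(row, col)` of the ROI's top-left pixel in its source
#'   image (1-based).
#' @param size ROI size in pixels, `c(rows, cols)` (default `c(200, 200)`).
#' @param block Block size in pixels (default `c(40, 40)`); must divide
#'   `size` exactly.
#' @return A `roi_grid` with fields `origin`, `size`, `block`, `n_blocks`.
#' @examples
#' g <- roi_grid()
#' g$n_blocks  # 25
#' @export
roi_grid <- function(origin = c(1L, 1L), size = c(200L, 200L),
                     block = c(40L, 40L)) {
  stopifnot(length(size) == 2L, length(block) == 2L,
            all(size > 0), all(block > 0))
  if (any(size %% block != 0))
    stop("ROI size must be divisible by the block size in both dimensions")
  structure(list(origin = as.integer(origin), size = as.integer(size),
                 block = as.integer(block),
                 n_blocks = as.integer(prod(size %/% block))),
            class = "roi_grid")
}

#' Extract the ROI window of an image
#' @param image Source image matrix.
#' @param grid A [roi_grid()]; its `origin` locates the window.
#' @export
crop_roi <- function(image, grid) {
  r0 <- grid$origin[1]; c0 <- grid$origin[2]
  if (r0 < 1 || c0 < 1 || r0 + grid$size[1] - 1 > nrow(image) ||
      c0 + grid$size[2] - 1 > ncol(image))
    stop("ROI does not fit inside the image")
  image[r0:(r0 + grid$size[1] - 1), c0:(c0 + grid$size[2] - 1)]
}

#' Block-wise binarization of a gray-level ROI
#'
#' Segments vessels by thresholding: a global Otsu threshold initializes
#' the segmentation, then (with `refinement = "per_block_otsu"`) each block
#' of the grid is re-thresholded at its own Otsu value, clamped to within
#' `clamp` times the ROI's value range of the global threshold. The clamped
#' per-block refinement is a reproducible surrogate for interactively
#' adjusting each block's threshold against its gray-level histogram, and
#' adapts the segmentation to slowly varying illumination. Blocks whose
#' gray-level spread falls below `min_contrast` times the ROI spread are
#' classified entirely as background, preventing thresholds hallucinated
#' from vessel-free blocks.
#'
#' @param roi_image Gray-level matrix with dimensions equal to `grid$size`.
#' @param grid A [roi_grid()].
#' @param polarity `"bright"` when vessels are brighter than background
#'   (reconstructed slices), `"dark"` when darker (projection films).
#' @param refinement `"per_block_otsu"` (default) or `"none"` (global
#'   threshold everywhere).
#' @param clamp Maximum deviation of a block threshold from the global one,
#'   as a fraction of the ROI value range (default 0.1); `clamp = 0`
#'   reproduces global thresholding exactly.
#' @param min_contrast Minimum block spread as a fraction of ROI spread
#'   (default 0.2) below which a block is marked all-background.
#' @return A `binary_mask`: list with `data` (0/1 integer matrix),
#'   `thresholds` (global value and per-block matrix), `polarity`,
#'   `opened = FALSE` and a `log` of per-block fallbacks.
#' @export
binarize_blocks <- function(roi_image, grid = roi_grid(size = dim(roi_image)),
                            polarity = c("bright", "dark"),
                            refinement = c("per_block_otsu", "none"),
                            clamp = 0.1, min_contrast = 0.2) {
  polarity <- match.arg(polarity)
  refinement <- match.arg(refinement)
  stopifnot(all(dim(roi_image) == grid$size), clamp >= 0, min_contrast >= 0)
  log <- character()
  rng <- range(roi_image)
  nbr <- grid$size[1] %/% grid$block[1]
  nbc <- grid$size[2] %/% grid$block[2]
  mask <- matrix(0L, grid$size[1], grid$size[2])
  thr_blocks <- matrix(NA_real_, nbr, nbc)
  if (diff(rng) == 0) {
    log <- c(log, "constant ROI: all background")
    return(structure(list(data = mask, grid = grid,
                          thresholds = list(global = NA_real_, blocks = thr_blocks),
                          polarity = polarity, opened = FALSE, log = log),
                     class = "binary_mask"))
  }
  global <- otsu_threshold(roi_image)
  span <- diff(rng)
  for (i in seq_len(nbr)) {
    for (j in seq_len(nbc)) {
      rows <- ((i - 1) * grid$block[1] + 1):(i * grid$block[1])
      cols <- ((j - 1) * grid$block[2] + 1):(j * grid$block[2])
      blk <- roi_image[rows, cols]
      bspread <- diff(range(blk))
      if (refinement == "per_block_otsu" && bspread < min_contrast * span) {
        thr_blocks[i, j] <- NA_real_  # all background
        log <- c(log, sprintf("block (%d,%d): low contrast, all background", i, j))
        next
      }
      thr <- if (refinement == "none") global
      else if (length(unique(as.numeric(blk))) < 2L) {
        log <- c(log, sprintf("block (%d,%d): constant, global threshold used", i, j))
        global
      } else {
        min(max(otsu_threshold(blk), global - clamp * span), global + clamp * span)
      }
      thr_blocks[i, j] <- thr
      mask[rows, cols] <- if (polarity == "bright") (blk > thr) + 0L
      else (blk < thr) + 0L
    }
  }
  structure(list(data = mask, grid = grid,
                 thresholds = list(global = global, blocks = thr_blocks),
                 polarity = polarity, opened = FALSE, log = log),
            class = "binary_mask")
}

#' Morphological opening of a binary vessel mask
#'
#' Opening (erosion then dilation) with a 3 x 3 square structuring element:
#' removes noise specks smaller than the element while preserving vessel
#' structures at least 3 pixels wide. `closing = TRUE` instead performs
#' dilation then erosion, provided for fidelity experiments with the
#' alternative operation order.
#'
#' @param mask A `binary_mask`, or a plain 0/1 matrix.
#' @param closing Perform closing instead of opening (default FALSE).
#' @return The processed mask, same class as the input; `opened` set.
#' @export
morph_open <- function(mask, closing = FALSE) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  stopifnot(all(m %in% c(0L, 1L)))
  brush <- EBImage::makeBrush(3L, shape = "box")
  out <- if (closing) EBImage::closing(m, brush) else EBImage::opening(m, brush)
  out <- matrix(as.integer(out > 0.5), nrow(m), ncol(m))
  if (inherits(mask, "binary_mask")) {
    mask$data <- out
    mask$opened <- TRUE
    mask
  } else out
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d, %d vessel pixels (%.1f%%), %s polarity%s\n",
              nrow(x$data), ncol(x$data), sum(x$data),
              100 * mean(x$data), x$polarity,
              if (x$opened) ", opened" else ""))
  invisible(x)
}
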