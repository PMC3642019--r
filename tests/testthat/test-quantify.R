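test_that("the angiographic score is the exact pixel-count ratio", {
  expect_equal(angiographic_score(matrix(0L, 200, 200)), 0)
  expect_equal(angiographic_score(matrix(1L, 200, 200)), 1)
  m <- matrix(0L, 200, 200)
  m[seq_len(1200)] <- 1L
  expect_identical(angiographic_score(m), 1200 / 40000)

  # counting-ratio exactness on random masks
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample.int(4000, 1)
    m <- matrix(0L, 80, 50)
    m[sample.int(4000, k)] <- 1L
    expect_identical(angiographic_score(m), k / 4000)
  }
  expect_error(angiographic_score(matrix(integer(0), 0, 0)), "empty")
})

test_that("the default sampling scheme yields 27 ROIs per group", {
  films <- replicate(9, matrix(runif(300 * 300), 300, 300), simplify = FALSE)
  pl <- sample_rois(films, roi_size = 60L, seed = 1)
  expect_equal(nrow(pl), 27L)
  expect_equal(unique(pl$angle_deg), c(0, 90, 180))
  expect_equal(max(pl$film_idx), 3L)
  expect_equal(max(pl$area_idx), 3L)

  # non-overlap within each film
  for (f in split(pl, interaction(pl$angle_deg, pl$film_idx))) {
    if (nrow(f) < 2) next
    d <- as.matrix(dist(f[, c("roi_row", "roi_col")], method = "maximum"))
    expect_true(all(d[upper.tri(d)] >= 60))
  }

  pl1 <- sample_rois(films[1], angles_deg = 0, films_per_angle = 1L,
                     areas_per_film = 1L, roi_size = 60L, seed = 1)
  expect_equal(nrow(pl1), 1L)

  expect_identical(sample_rois(films, roi_size = 60L, seed = 9),
                   sample_rois(films, roi_size = 60L, seed = 9))
})

test_that("infeasible ROI requests fail with the feasible count", {
  films <- list(matrix(0.5, 70, 70))
  expect_error(sample_rois(films, angles_deg = 0, films_per_angle = 1L,
                           areas_per_film = 3L, roi_size = 60L, seed = 1),
               "at most 1 fit")
  expect_error(sample_rois(films, angles_deg = 0, films_per_angle = 1L,
                           areas_per_film = 1L, roi_size = 100L, seed = 1),
               "too small")
})

test_that("films are drawn from adjacent angles around each nominal view", {
  ph <- blob_phantom(n = 48L, nz = 70L)
  ps <- project(ph, angles_deg = 0:179)
  pl <- sample_rois(ps, roi_size = 20L, seed = 2)
  for (a in c(0, 90)) {
    ids <- sort(unique(pl$film_id[pl$angle_deg == a]))
    expect_true(all(abs(ps$angles_deg[ids] %% 180 - a) <= 1 |
                      abs(ps$angles_deg[ids] %% 180 - a) >= 179))
  }
  # the nominal 180-degree view maps to the 179-degree projection
  ids180 <- unique(pl$film_id[pl$angle_deg == 180])
  expect_true(179L %in% ps$angles_deg[ids180])
})

test_that("group summaries use the sample standard deviation", {
  g <- score_group(rep(0.2, 27))
  expect_equal(g$mean, 0.2)
  expect_equal(g$sd, 0)
  expect_equal(g$n, 27L)

  g2 <- score_group(c(0.1, 0.3))
  expect_equal(g2$mean, 0.2)
  expect_equal(g2$sd, sqrt(0.02))
  expect_error(score_group(0.5), "at least 2")
})

test_that("line profiles interpolate bilinearly along the segment", {
  img <- matrix(0.7, 30, 30)
  p <- extract_profile(img, c(5, 3), c(5, 27))
  expect_true(all(p$values == 0.7))
  expect_equal(p$positions, 0:24)

  # reversal flips the values
  grad <- matrix(seq(0, 1, length.out = 30), 30, 30, byrow = TRUE)
  fwd <- extract_profile(grad, c(10, 2), c(10, 28))
  rev <- extract_profile(grad, c(10, 28), c(10, 2))
  expect_equal(rev$values, rev(fwd$values), tolerance = 1e-12)

  expect_error(extract_profile(img, c(5, 5), c(5, 5)), "zero-length")
  expect_error(extract_profile(img, c(0, 5), c(5, 5)), "outside")
})

test_that("profiles across a cylinder projection match the chord form", {
  ph <- cylinder_phantom(n = 128L, nz = 3L, radius_um = 135)
  np <- normalize_projections(project(ph, angles_deg = 0))
  prof <- extract_profile(np$images[[1]], c(2, 1), c(2, 128))
  chord <- chord_profile(128L, 135)
  expect_lt(sqrt(mean((prof$values - chord)^2)) / max(chord), 0.02)
})

test_that("FWHM diameters scale exactly with the 9-um pixel pitch", {
  # an ideal rectangular dip of width 5 px measures 5 px = 45 um
  v <- rep(1, 41)
  v[19:23] <- 0
  d <- measure_diameter(v, pixel_pitch_um = 9)
  expect_equal(d$pixel_count, 5)
  expect_equal(d$diameter_um, 45)

  # a Gaussian dip of sigma = 2 px has FWHM 2.355 * sigma = 4.71 px
  x <- 1:61
  vg <- 1 - 0.5 * exp(-(x - 31)^2 / (2 * 2^2))
  dg <- measure_diameter(vg, pixel_pitch_um = 9)
  expect_equal(dg$pixel_count, 2 * sqrt(2 * log(2)) * 2, tolerance = 0.03)

  # diameter_um is pixel_count * pitch exactly
  expect_identical(dg$diameter_um, dg$pixel_count * 9)

  # flat profile: no vessel
  expect_error(measure_diameter(rep(1, 30) + rnorm(30, 0, 1e-4)),
               "no vessel")
})

test_that("a 7.8-pixel vessel at 9 um per pixel reads as about 70 um", {
  # profile constructed with half-depth crossings exactly 7.8 px apart
  sigma <- 7.8 / (2 * sqrt(2 * log(2)))
  x <- seq_len(81)
  v <- 1 - 0.4 * exp(-(x - 41)^2 / (2 * sigma^2))
  d <- measure_diameter(v, pixel_pitch_um = 9)
  expect_equal(d$pixel_count, 7.8, tolerance = 0.01)
  expect_equal(signif(d$diameter_um, 2), 70)
  expect_match(format(d), "^70 um")
})

test_that("tube diameters of 3-25 px are recovered within one pixel", {
  errs <- c()
  for (seed in 1:20) {
    for (d_px in c(3, 5, 9, 14, 20, 25)) {
      img <- tube_band_image(d_px, n = 64L, blur_sigma = 0.7,
                             noise_sd = 0.01, seed = seed)
      prof <- extract_profile(img, c(32, 1), c(32, 64))
      m <- measure_diameter(prof, pixel_pitch_um = 9, noise_floor = 3)
      errs <- c(errs, m$pixel_count - d_px)
    }
  }
  expect_lt(max(abs(errs)), 1)
})

test_that("scored ROI tables carry the segmentation through", {
  films <- lapply(1:9, function(i) {
    roi <- matrix(0.2, 160, 160)
    roi[, seq(10, 150, by = 16)] <- 0.8
    roi + matrix(rnorm(160^2, 0, 0.02), 160, 160)
  })
  pl <- sample_rois(films, roi_size = 40L, seed = 3)
  tab <- score_rois(films, pl, roi_size = 40L, block = 8L,
                    polarity = "bright")
  expect_equal(nrow(tab), 27L)
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  # one-pixel stripes every 16 columns are opened away unless widened;
  # with opening disabled the designed stripe fraction (1/16) is seen
  tab2 <- score_rois(films, pl, roi_size = 40L, block = 8L,
                     polarity = "bright", open = FALSE)
  expect_equal(mean(tab2$score), 1 / 16, tolerance = 0.3)
})

test_that("noiseless sweeps detect the smallest swept diameter in both modes", {
  for (mode in c("absorption", "phase")) {
    res <- suppressWarnings(
      min_detectable_diameter(c(18, 36, 72), mode = mode, n_reps = 1L,
                              seed = 1))
    expect_equal(res$min_detectable_um, 18)
    expect_true(res$at_sweep_floor)
  }
  # a sweep starting above the true limit returns its floor, flagged
  res90 <- suppressWarnings(
    min_detectable_diameter(c(90, 135), mode = "absorption", n_reps = 1L,
                            seed = 1))
  expect_equal(res90$min_detectable_um, 90)
  expect_true(res90$at_sweep_floor)
})

test_that("end-to-end score recovery hits the designed lumen fraction", {
  # one group, designed fraction 0.2, full chain at 192^2
  f <- 0.2
  lt <- lattice_tree(f, n_px = 192L, nz_px = 2L)
  ph <- suppressWarnings(voxelize(lt$tree, 9, dim = c(192L, 192L, 2L)))
  ps <- project(ph, 0:179, flat = flat_field_model(0.1),
                noise = noise_model(photons = 5000, read_sd = 0.005),
                seed = 4)
  vol <- reconstruct_volume(ps, rows = 1:2)
  pl <- sample_rois(vol$slices, angles_deg = c(0, 90), films_per_angle = 1L,
                    areas_per_film = 1L, roi_size = 80L, bbox = lt$bbox,
                    seed = 5)
  tab <- score_rois(vol$slices, pl, roi_size = 80L, block = 16L,
                    polarity = "bright")
  expect_lt(abs(mean(tab$score) - f), 0.03)
})
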