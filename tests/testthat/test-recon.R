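test_that("normalization is the exact negative log-ratio", {
  ph <- blob_phantom(n = 32L)
  ff <- flat_field_model(nonuniformity = 0.15)
  ps <- project(ph, angles_deg = c(0, 90), flat = ff)
  np <- normalize_projections(ps)
  expect_identical(np$domain, "attenuation")
  # hand-computed -log(I / I0)
  I0 <- (ps$background$pre + ps$background$post) / 2
  expect_equal(np$images[[1]], pmax(-log(ps$images[[1]] / I0), 0))

  # a single pixel at I0 * exp(-1) normalizes to exactly 1
  flat_ps <- project(structure(list(grid = array(0, c(8, 8, 1)),
                                    voxel_size_um = 9, origin = c(0, 0, 0),
                                    log = character()),
                               class = "voxel_phantom"), angles_deg = 0)
  flat_ps$images[[1]][1, 3] <- exp(-1)
  out <- normalize_projections(flat_ps)$images[[1]]
  expect_equal(out[1, 3], 1)
  expect_equal(sum(out != 0), 1L)
})

test_that("non-positive intensities are repaired from neighbours and logged", {
  ps <- project(blob_phantom(n = 16L, nz = 12L), angles_deg = 0)
  ps$images[[1]][4, 7] <- 0
  ps$images[[1]][9, 2] <- -0.2
  np <- normalize_projections(ps)
  expect_true(all(is.finite(np$images[[1]])))
  expect_match(np$log, "2 non-positive", all = FALSE)
})

test_that("normalized cylinder profiles match the chord-length oracle", {
  ph <- cylinder_phantom(n = 128L, nz = 2L, radius_um = 180)
  ps <- project(ph, angles_deg = 0:179, flat = flat_field_model(0.1))
  np <- normalize_projections(ps)
  chord <- chord_profile(128L, 180)
  prof <- np$images[[45]][1, ]
  expect_lt(sqrt(mean((prof - chord)^2)) / max(chord), 0.02)
})

test_that("sinogram assembly is an exact row permutation", {
  ph <- blob_phantom(n = 32L, nz = 3L)
  np <- normalize_projections(project(ph, angles_deg = 0:179))
  sino <- assemble_sinogram(np, 2L)
  expect_equal(dim(sino$data), c(180L, 32L))
  for (a in c(1L, 60L, 180L))
    expect_identical(sino$data[a, ], np$images[[a]][2L, ])
  expect_error(assemble_sinogram(np, 4L), "outside detector rows")

  const <- np
  const$images <- lapply(const$images, function(I) I * 0 + 0.3)
  expect_true(all(assemble_sinogram(const, 1L)$data == 0.3))
})

test_that("rotation-axis offsets are recovered to sub-pixel accuracy", {
  ph <- blob_phantom(n = 64L)
  sino <- assemble_sinogram(normalize_projections(project(ph, 0:179)), 1L)
  expect_lt(abs(estimate_axis(sino)), 0.1 + 1e-9)
  for (shift in c(-5, -3.3, -1.5, 0.7, 3, 5)) {
    est <- estimate_axis(shift_sinogram(sino, shift))
    expect_lt(abs(est - shift), 0.2 + 1e-9)
  }
  zero <- sino
  zero$data[] <- 0
  expect_error(estimate_axis(zero), "no signal")
})

scale_sino <- function(s, a) { s$data <- a * s$data; s }

test_that("FBP is linear and inverts simple phantoms", {
  ph <- blob_phantom(n = 64L)
  sino <- assemble_sinogram(normalize_projections(project(ph, 0:179)), 1L)
  zero <- sino
  zero$data[] <- 0
  expect_true(all(fbp(zero) == 0))
  expect_equal(fbp_scaled <- fbp(scale_sino(sino, 3.5)), 3.5 * fbp(sino),
               tolerance = 1e-9)

  # point impulse localizes within one voxel
  imp <- array(0, c(64, 64, 1))
  imp[20, 45, 1] <- 0.01
  php <- structure(list(grid = imp, voxel_size_um = 9, origin = c(0, 0, 0),
                        log = character()), class = "voxel_phantom")
  sl <- fbp(assemble_sinogram(normalize_projections(project(php, 0:179)), 1L))
  w <- which(sl == max(sl), arr.ind = TRUE)
  expect_lte(max(abs(w - c(20, 45))), 1L)

  expect_error(fbp(sino, "butterworth"), "ramlak")
})

test_that("noiseless cylinder reconstruction reaches NRMSE < 0.10", {
  ph <- cylinder_phantom(n = 128L, nz = 1L, radius_um = 180)
  sino <- assemble_sinogram(normalize_projections(project(ph, 0:179)), 1L)
  sl <- fbp(sino)
  gt <- attenuation_slice(ph, 1L)
  supp <- gt > 0
  expect_lt(sqrt(mean((sl[supp] - gt[supp])^2)) / mean(gt[supp]), 0.10)
})

test_that("FBP matches the brute-force back-projection oracle", {
  ph <- blob_phantom(n = 48L)
  sino <- assemble_sinogram(normalize_projections(project(ph, 0:179)), 1L)
  for (filt in c("ramlak", "hann")) {
    mine <- fbp(sino, filt)
    oracle <- brute_force_fbp(sino$data, sino$angles_deg, filt)
    rel_rms <- sqrt(mean((mine - oracle)^2)) / sqrt(mean(oracle^2))
    expect_lt(rel_rms, 1e-6)
  }
})

test_that("reconstruction fidelity improves with angle count", {
  ph <- cylinder_phantom(n = 64L, nz = 1L, radius_um = 90)
  gt <- attenuation_slice(ph, 1L)
  # measure over the reconstruction disk excluding the cylinder's edge
  # ring: the partial-volume error there is angle-independent and would
  # mask the angular-sampling error this property is about
  rr <- sqrt(outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+"))
  region <- rr < 30 & abs(rr - 10) >= 2
  nrmse <- vapply(c(45L, 90L, 180L), function(na) {
    ang <- seq(0, 179.999, length.out = na + 1)[seq_len(na)]
    ang <- floor(ang * 10) / 10
    ps <- project(ph, angles_deg = ang)
    sl <- fbp(assemble_sinogram(normalize_projections(ps), 1L))
    sqrt(mean((sl[region] - gt[region])^2)) / mean(gt[gt > 0])
  }, numeric(1))
  expect_true(all(diff(nrmse) < 0))
})

test_that("background equalization is shift-invariant and warns on constants", {
  ph <- blob_phantom(n = 64L)
  sl <- fbp(assemble_sinogram(normalize_projections(project(ph, 0:179)), 1L))
  e1 <- equalize_background(sl)
  e2 <- equalize_background(sl + 0.3)
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-6)
  expect_equal(attr(e1, "background_gray"), 0.5)

  expect_warning(same <- equalize_background(matrix(2, 8, 8)), "degenerate")
  expect_equal(as.numeric(same), rep(2, 64))
})

test_that("equalization aligns slices acquired under different flat fields", {
  ph <- cylinder_phantom(n = 64L, nz = 1L, radius_um = 90)
  recon_one <- function(ff) {
    ps <- project(ph, 0:179, flat = ff)
    equalize_background(
      fbp(assemble_sinogram(normalize_projections(ps), 1L)))
  }
  s1 <- recon_one(flat_field_model(nonuniformity = 0.05))
  s2 <- recon_one(flat_field_model(nonuniformity = 0.3, vignette = 0.2,
                                   seed = 4))
  n <- 64
  r <- sqrt(outer((1:n - 32.5)^2, (1:n - 32.5)^2, "+"))
  bg <- r > 0.55 * 32 & r < 0.85 * 32
  gray_range <- diff(range(s1))
  expect_lt(abs(median(s1[bg]) - median(s2[bg])), 0.02 * gray_range)
})

test_that("volume reconstruction maps rows to slices with provenance", {
  ph <- blob_phantom(n = 32L, nz = 6L)
  ps <- project(ph, angles_deg = 0:89 * 2, group_id = "CT2")
  vol <- reconstruct_volume(ps)
  expect_length(vol$slices, 6L)
  two <- reconstruct_volume(ps, rows = c(2L, 5L))
  expect_length(two$slices, 2L)
  expect_equal(two$rows, c(2L, 5L))
  expect_equal(two$provenance, "CT2")
  expect_equal(two$filter, "ramlak")
})

test_that("reconstructed lumens are brighter than the background", {
  lt <- lattice_tree(0.16, n_px = 128L, nz_px = 2L)
  ph <- suppressWarnings(voxelize(lt$tree, 9, dim = c(128L, 128L, 2L)))
  ps <- project(ph, 0:179, flat = flat_field_model(0.1))
  vol <- reconstruct_volume(ps, rows = 1L)
  sl <- vol$slices[[1]]
  lumen <- ph$grid[, , 1] > 0
  n <- 128
  r <- sqrt(outer((1:n - 64.5)^2, (1:n - 64.5)^2, "+"))
  bg_level <- median(sl[!lumen & r < 60])
  lumen_amp <- attenuation_slice(ph, 1L)[lumen][1]
  expect_gt(mean(sl[lumen] > bg_level + lumen_amp / 2), 0.95)
})
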