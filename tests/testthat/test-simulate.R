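test_that("identical spec and seed give bit-identical images and truths", {
  a <- top_image(offset = 15, seed = 99, orientation_deg = 33)
  b <- top_image(offset = 15, seed = 99, orientation_deg = 33)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth, b$truth)
  l1 <- generate_lateral_view(centriole_spec("lateral"), img_noisy(5))
  l2 <- generate_lateral_view(centriole_spec("lateral"), img_noisy(5))
  expect_identical(l1$image$channels, l2$image$channels)
})

test_that("noise-free top view is centred and rotation leaves flux unchanged", {
  o <- top_image(noise = FALSE)
  m <- o$image$channels$tubulin
  gx <- seq_len(nrow(m)); gy <- seq_len(ncol(m))
  cen <- c(sum(rowSums(m) * gx), sum(colSums(m) * gy)) / sum(m)
  expect_lt(max(abs(cen - o$image$meta$center_px)), 0.1)
  tot0 <- sum(m)
  for (ang in c(13, 40, 111)) {
    mi <- top_image(noise = FALSE, orientation_deg = ang)$image$channels$tubulin
    expect_lt(abs(sum(mi) - tot0) / tot0, 0.005)
  }
})

test_that("zero protein offset puts both channel maxima at the same radius", {
  o <- top_image(offset = 0, noise = FALSE)
  sp <- extract_spokes(o$image, o$image$meta$center_px)
  for (s in sp) {
    expect_equal(s$radii_nm[which.max(s$tubulin)],
                 s$radii_nm[which.max(s$protein)])
  }
})

test_that("lateral band geometry follows coverage and position by construction", {
  o <- generate_lateral_view(
    centriole_spec("lateral", tubulin_length_nm = 450,
                   protein_coverage_frac = 1, protein_position_frac = 0),
    img_clean(3))
  ap <- axial_profile(o$image)
  lt <- measure_length(ap, "tubulin")
  lp <- measure_length(ap, "protein")
  expect_equal(lp$length_nm, lt$length_nm, tolerance = 0.03)
  # half-coverage band at 25 %: edges at 25 % and 75 % of the extent
  o2 <- generate_lateral_view(
    centriole_spec("lateral", tubulin_length_nm = 450,
                   protein_coverage_frac = 0.5, protein_position_frac = 0.25),
    img_clean(3))
  expect_equal(o2$truth$coverage_pct, 50)
  expect_equal(o2$truth$position_frac, 0.25)
  ap2 <- axial_profile(o2$image)
  lt2 <- measure_length(ap2, "tubulin")
  lp2 <- measure_length(ap2, "protein")
  expect_equal((lp2$start_nm - lt2$start_nm) / lt2$length_nm, 0.25,
               tolerance = 0.02)
  expect_equal((lp2$end_nm - lt2$start_nm) / lt2$length_nm, 0.75,
               tolerance = 0.02)
})

test_that("manifest truths equal requested fixed parameters and round-trip", {
  sim <- simulate_centrioles("hs-control", n = 4, view = "top",
                             channel = "POC5", seed = 21)
  expect_equal(sim$manifest$true_delta_nm, rep(27, 4))
  expect_equal(sim$manifest$wall_radius_nm, rep(110, 4))
  expect_false(any(sim$manifest$broken))
  path <- file.path(tempdir(), "manifest_test")
  write_manifest(sim$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$true_delta_nm, sim$manifest$true_delta_nm)
  expect_equal(back$orientation_deg, sim$manifest$orientation_deg,
               tolerance = 1e-12)
  expect_equal(back$image_id, sim$manifest$image_id)
})

test_that("images survive a TIFF round-trip with metadata", {
  o <- top_image(offset = 12, seed = 7)
  path <- file.path(tempdir(), "roundtrip.tif")
  write_centriole_tiff(o$image, path)
  back <- read_centriole_tiff(path)
  expect_equal(names(back$channels), c("tubulin", "protein"))
  expect_equal(back$calib$x_factor, o$image$calib$x_factor)
  # 16-bit storage: integer counts preserved exactly (values are < 2^16)
  expect_equal(back$channels$tubulin,
               pmax(round(o$image$channels$tubulin), 0),
               ignore_attr = TRUE)
})

test_that("field of view and packing violations error", {
  expect_error(generate_top_view(centriole_spec("top"), img_clean(), fov_px = 10),
               "geometry")
  expect_error(
    generate_cell_field(4, foci_per_cell = 500, imaging = img_noisy(1)),
    "packing")
})

test_that("cell-field truths record the requested counts and groups", {
  f <- generate_cell_field(10, foci_per_cell = 2, imaging = img_noisy(2))
  expect_equal(f$truth$count_ch1, rep(2L, 10))
  expect_equal(sort(unique(as.vector(f$cells[f$cells > 0]))), 1:10)
  f2 <- generate_cell_field(10, foci_per_cell = 2, intensity_ratio = 0.5,
                            imaging = img_noisy(2))
  expect_equal(sum(f2$truth$group == "treated"), 5)
  expect_equal(unique(f2$truth$intensity_factor[f2$truth$group == "treated"]), 0.5)
})

test_that("noise-free decoration profile is exactly periodic", {
  p <- generate_decoration_profile(
    decoration_profile_spec(8, 15, noise_sd = 0, sample_step_nm = 0.5))
  y <- p$profile$intensity
  d <- y - mean(y)
  ac <- stats::acf(d, lag.max = 40, plot = FALSE)$acf[-1]
  # dominant non-zero lag (excluding the trivially correlated short lags)
  lag_band <- 8:40
  expect_equal(lag_band[which.max(ac[lag_band])] * 0.5, 8)
  expect_error(decoration_profile_spec(8, 10, sample_step_nm = 3),
               "sample_step")
})
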