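lat_image <- function(length_nm = 450, cov = 0.5, pos = 0.25, seed = 3,
                      noise = FALSE, ...) {
  generate_lateral_view(
    centriole_spec("lateral", tubulin_length_nm = length_nm,
                   protein_coverage_frac = cov, protein_position_frac = pos,
                   ...),
    if (noise) img_noisy(seed) else img_clean(seed))
}

test_that("axial profile is rotation invariant and plateau-shaped", {
  l0 <- lat_image(orientation_deg = 0)
  l30 <- lat_image(orientation_deg = 30)
  ap0 <- axial_profile(l0$image)
  ap30 <- axial_profile(l30$image)
  t0 <- measure_length(ap0, "tubulin")$length_nm
  t30 <- measure_length(ap30, "tubulin")$length_nm
  expect_lt(abs(t30 - t0) / t0, 0.01)
  # plateau: central 50 % of the profile varies little relative to its max
  y <- ap0$channels$tubulin
  core <- y[y > 0.9 * max(y)]
  expect_gt(length(core), 10)
  expect_error(axial_profile(top_image(noise = FALSE)$image), "ambiguous axis")
})

test_that("length is accurate, scale invariant and monotone in truth", {
  l <- lat_image(length_nm = 450)
  ap <- axial_profile(l$image)
  lt <- measure_length(ap, "tubulin")
  expect_equal(lt$length_nm, 450, tolerance = 5)
  # intensity rescaling leaves the measurement unchanged
  img2 <- l$image
  img2$channels <- lapply(img2$channels, function(m) 3.7 * m)
  lt2 <- measure_length(axial_profile(img2), "tubulin")
  expect_equal(lt2$length_nm, lt$length_nm, tolerance = 1e-6)
  # strict monotonicity on noise-free images
  lens <- vapply(c(300, 380, 450, 520), function(L) {
    measure_length(axial_profile(lat_image(length_nm = L)$image),
                   "tubulin")$length_nm
  }, numeric(1))
  expect_true(all(diff(lens) > 0))
  flat <- structure(list(positions_nm = 1:100,
                         channels = list(tubulin = rep(1, 100))),
                    class = "axial_profile",
                    calib = expansion_calibration(50.4))
  expect_error(measure_length(flat, "tubulin"), "no signal")
})

test_that("coverage arithmetic reproduces the recorded length pairs", {
  mk <- function(len, start = 0) {
    structure(list(channel = "x", length_nm = len, start_nm = start,
                   end_nm = start + len, threshold_fraction = 0.5),
              class = "length_measurement")
  }
  cases <- list(c(204, 495, 41), c(200, 497, 40), c(200, 432, 46))
  for (cs in cases) {
    cv <- coverage_and_position(mk(cs[2]), mk(cs[1], start = 100))
    expect_equal(round(cv$coverage_pct), cs[3])
  }
  cv_full <- coverage_and_position(mk(400), mk(400))
  expect_equal(cv_full$coverage_pct, 100)
  expect_equal(cv_full$position_pct, 50)
  expect_error(coverage_and_position(mk(0), mk(10)), "division")
})

test_that("regions follow the control and depleted rules", {
  mk <- function(len, start = 0) {
    structure(list(channel = "x", length_nm = len, start_nm = start,
                   end_nm = start + len, threshold_fraction = 0.5),
              class = "length_measurement")
  }
  tub <- mk(400)
  band <- mk(200, start = 100)   # 25 % to 75 %
  rg <- define_regions(tub, band)
  expect_equal(rg$position_nm, c(50, 200, 350))
  # depleted: distal region is the last 100 nm
  tub5 <- mk(500)
  belt <- mk(100, start = 50)
  rgd <- define_regions(tub5, belt, depleted = TRUE)
  expect_equal(unlist(rgd[rgd$region == "distal", c("start_nm", "end_nm")]),
               c(start_nm = 400, end_nm = 500))
  expect_error(define_regions(tub, mk(400)), "full tubulin extent")
  expect_error(define_regions(tub, NULL), "cannot define")
})

test_that("diameter recovers the wall separation in every region", {
  l <- lat_image(length_nm = 500, cov = 0.5, pos = 0.25)
  ap <- axial_profile(l$image)
  lt <- measure_length(ap, "tubulin")
  lp <- measure_length(ap, "protein")
  rg <- define_regions(lt, lp)
  for (r in rg$region) {
    d <- measure_diameter(l$image, ap, rg, r)
    expect_equal(d$diameter_nm, 220, tolerance = 5)
  }
  # intensity scaling leaves the diameter unchanged
  img2 <- l$image
  img2$channels <- lapply(img2$channels, function(m) 2 * m)
  d2 <- measure_diameter(img2, axial_profile(img2), rg, "core")
  d1 <- measure_diameter(l$image, ap, rg, "core")
  expect_equal(d2$diameter_nm, d1$diameter_nm, tolerance = 0.5)
  # elliptical barrel viewed along the major axis: minor-axis separation
  le <- lat_image(length_nm = 500, ellipse_ratio = 0.8)
  ape <- axial_profile(le$image)
  rge <- define_regions(measure_length(ape, "tubulin"),
                        measure_length(ape, "protein"))
  de <- measure_diameter(le$image, ape, rge, "core")
  expect_equal(de$diameter_nm, 0.8 * 220, tolerance = 5)
})

test_that("scan position within a homogeneous region does not move the diameter", {
  l <- lat_image(length_nm = 500)
  ap <- axial_profile(l$image)
  lt <- measure_length(ap, "tubulin")
  lp <- measure_length(ap, "protein")
  rg <- define_regions(lt, lp)
  core <- rg[rg$region == "core", ]
  d0 <- measure_diameter(l$image, ap, rg, "core")$diameter_nm
  for (shift in c(-30, 30)) {
    rg2 <- rg
    rg2$position_nm[rg2$region == "core"] <- core$position_nm + shift
    d1 <- measure_diameter(l$image, ap, rg2, "core")$diameter_nm
    expect_lt(abs(d1 - d0), 2)
  }
})
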