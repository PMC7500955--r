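test_that("ring centre is found accurately and equivariantly", {
  o <- top_image(noise = FALSE)
  ctr <- find_center(o$image)
  expect_lt(max(abs(ctr - o$image$meta$center_px)), 0.1)
  # integer translation moves the estimate by exactly the shift
  m <- o$image$channels$tubulin
  sh <- matrix(0, nrow(m) + 10, ncol(m) + 10)
  sh[8:(7 + nrow(m)), 3:(2 + ncol(m))] <- m
  expect_lt(max(abs(find_center(sh) - (ctr + c(7, 2)))), 0.2)
  # 60-degree break: centre still within 1 px of truth
  ob <- top_image(noise = FALSE, break_arc_deg = 60, break_start_deg = 80)
  expect_lt(max(abs(find_center(ob$image) - ob$image$meta$center_px)), 1)
  expect_error(find_center(matrix(1, 30, 30)), "empty image")
})

test_that("spoke profiles reflect the wall geometry", {
  # uniform image: every spoke profile is constant
  u <- matrix(5, 40, 40)
  sp <- extract_spokes(u, c(20.5, 20.5), angles_deg = c(0, 45, 200),
                       calib = expansion_calibration(50.4))
  for (s in sp) expect_lt(diff(range(s$tubulin)), 1e-9)
  # noise-free ring: unimodal spokes peaking at the wall radius (the PSF on
  # the curved wall biases the peak inward by about 1 nm at this radius)
  o <- top_image(noise = FALSE)
  res <- measure_triplet_offsets(extract_spokes(o$image, find_center(o$image)))
  expect_equal(length(res$offsets$r_tubulin_nm), 9)
  expect_true(all(abs(res$offsets$r_tubulin_nm - 110) < 2))
  # a 40-degree rotation of a 9-triplet ring maps spoke angles onto themselves
  o2 <- top_image(noise = FALSE, orientation_deg = 40)
  ang1 <- sort(vapply(extract_spokes(o$image, find_center(o$image)),
                      `[[`, numeric(1), "angle_deg"))
  ang2 <- sort(vapply(extract_spokes(o2$image, find_center(o2$image)),
                      `[[`, numeric(1), "angle_deg"))
  expect_equal(ang1, ang2, tolerance = 2)
  expect_error(extract_spokes(o$image, c(500, 500)), "center outside")
})

test_that("triplet offsets recover the rendered shell offset with sign", {
  # coincident shell: near-zero mean over a small batch
  d0 <- unlist(lapply(1:6, function(i) {
    o <- top_image(offset = 0, seed = 200 + i, orientation_deg = 37 * i)
    r <- measure_triplet_offsets(extract_spokes(o$image, find_center(o$image)))
    r$offsets$delta_nm[r$offsets$resolved]
  }))
  expect_lt(abs(mean(d0)), 2)
  # exterior shell: negative offset of the right magnitude
  oe <- top_image(offset = -10, seed = 31)
  re <- measure_triplet_offsets(extract_spokes(oe$image, find_center(oe$image)))
  expect_equal(re$mean_delta_nm, -10, tolerance = 3)
  # interior shell 27 nm
  oi <- top_image(offset = 27, seed = 32)
  ri <- measure_triplet_offsets(extract_spokes(oi$image, find_center(oi$image)))
  expect_equal(ri$mean_delta_nm, 27, tolerance = 3)
  expect_true(all(abs(ri$offsets$delta_nm[ri$offsets$resolved]) <= 60))
})

test_that("mean offset is invariant to rotation and translation", {
  base <- top_image(offset = 22, seed = 77)
  m0 <- measure_triplet_offsets(
    extract_spokes(base$image, find_center(base$image)))$mean_delta_nm
  rot <- generate_top_view(
    centriole_spec("top", protein_offset_nm = 22, orientation_deg = 61),
    imaging_spec(seed = 77))
  m1 <- measure_triplet_offsets(
    extract_spokes(rot$image, find_center(rot$image)))$mean_delta_nm
  expect_lt(abs(m1 - m0), 1.5)
  # integer-pixel translation of the same image
  img <- base$image
  pad <- function(m) {
    sh <- matrix(stats::median(m), nrow(m) + 9, ncol(m) + 9)
    sh[6:(5 + nrow(m)), 4:(3 + ncol(m))] <- m
    sh
  }
  img$channels <- lapply(img$channels, pad)
  m2 <- measure_triplet_offsets(
    extract_spokes(img, find_center(img)))$mean_delta_nm
  expect_lt(abs(m2 - m0), 1)
})

test_that("recovered offsets regress on truth with unit slope", {
  trues <- c(0, 12, 22, 28)
  recovered <- vapply(trues, function(d) {
    mean(unlist(lapply(1:5, function(i) {
      o <- top_image(offset = d, seed = 400 + 10 * d + i,
                     orientation_deg = (29 * i) %% 360)
      r <- measure_triplet_offsets(extract_spokes(o$image, find_center(o$image)))
      r$offsets$delta_nm[r$offsets$resolved]
    })))
  }, numeric(1))
  fit <- stats::lm(recovered ~ trues)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.05)
  expect_lt(abs(unname(stats::coef(fit)[1])), 2)
})

test_that("aggregation pools per-measurement offsets faithfully", {
  o1 <- top_image(offset = 15, seed = 51)
  o2 <- top_image(offset = 15, seed = 52)
  r1 <- measure_triplet_offsets(extract_spokes(o1$image, find_center(o1$image)))
  r2 <- measure_triplet_offsets(extract_spokes(o2$image, find_center(o2$image)))
  # single result passes through
  a1 <- aggregate_offsets(list(r1), "g")
  expect_equal(a1$mean_delta_nm, r1$mean_delta_nm)
  expect_equal(a1$n, r1$n_measurements)
  # duplicated result doubles n, keeps the mean
  a2 <- aggregate_offsets(list(r1, r1), c("g", "g"))
  expect_equal(a2$mean_delta_nm, r1$mean_delta_nm)
  expect_equal(a2$n, 2 * r1$n_measurements)
  # pooled mean equals the brute-force mean of concatenated offsets
  a3 <- aggregate_offsets(list(r1, r2), c("g", "g"))
  brute <- mean(c(r1$offsets$delta_nm[r1$offsets$resolved],
                  r2$offsets$delta_nm[r2$offsets$resolved]))
  expect_equal(a3$mean_delta_nm, brute)
})
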