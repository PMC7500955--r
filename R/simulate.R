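#' Imaging model for the synthetic generator
#'
#' Describes the (simplified) confocal acquisition applied to rendered
#' centrioles: an isotropic Gaussian PSF, Poisson photon statistics, additive
#' Gaussian read noise and a constant background offset. The PSF is specified
#' in expanded-space nm, i.e. at the scale the camera sees.
#'
#' @param psf_fwhm_nm Gaussian PSF full width at half maximum, expanded-space
#'   nm (default 140).
#' @param photon_scale Expected photon count at the brightest structure pixel
#'   (default 200).
#' @param read_noise_sd SD of additive Gaussian read noise, counts (default 2).
#' @param background Constant background offset, counts (default 5).
#' @param calib An [expansion_calibration()]; defaults to a 50.4 mm gel
#'   (expansion factor 4.2) at 35 nm pixels.
#' @param seed Integer seed controlling all random draws.
#' @param noise If `FALSE`, generators return the noise-free expected image
#'   (scaled to `photon_scale`, no background): useful for geometry tests.
#' @return An object of class `imaging_spec`.
#' @export
imaging_spec <- function(psf_fwhm_nm = 140, photon_scale = 200,
                         read_noise_sd = 2, background = 5,
                         calib = expansion_calibration(50.4), seed = 1L,
                         noise = TRUE) {
  stopifnot(psf_fwhm_nm > 0, photon_scale > 0, read_noise_sd >= 0,
            background >= 0, inherits(calib, "expansion_calibration"))
  structure(list(psf_fwhm_nm = psf_fwhm_nm, photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd, background = background,
                 calib = calib, seed = as.integer(seed), noise = noise),
            class = "imaging_spec")
}

#' Geometry of one synthetic expanded centriole
#'
#' Parameters are biological nm (they are multiplied by the gel expansion
#' factor at render time). The microtubule wall is rendered as a dense ring
#' (top view) or two lateral wall lines (lateral view) with a nine-fold
#' amplitude modulation marking the triplet positions; the protein of
#' interest is rendered with the same geometry displaced radially by
#' `protein_offset_nm` toward the lumen (positive offsets).
#'
#' @param view `"top"` or `"lateral"`.
#' @param wall_radius_nm Radius of the tubulin wall intensity peak (default 110).
#' @param n_triplets Number of microtubule triplets (default 9).
#' @param tubulin_length_nm Length-2 numeric `c(mean, sd)` of the barrel
#'   length (lateral view); a single number means SD 0.
#' @param protein_offset_nm Radial offset of the protein shell, positive
#'   toward the lumen (default 0).
#' @param protein_coverage_frac Fraction of the tubulin length covered by the
#'   protein band (lateral view); `c(mean, sd)` for a truncated-normal draw.
#' @param protein_position_frac Axial position of the band's proximal edge as
#'   a fraction of tubulin length; `NA` centres the band.
#' @param ellipse_ratio Minor/major axis ratio of the wall cross-section
#'   (1 = round).
#' @param break_arc_deg Angular extent of missing wall, degrees (0 = intact).
#' @param break_start_deg Start angle of the break (parametric, degrees).
#' @param break_axial_range_frac Length-2 fraction interval of the axis over
#'   which the wall is removed (lateral view; default whole axis).
#' @param orientation_deg In-plane orientation of the centriole.
#' @param mod_depth Nine-fold amplitude modulation depth of the wall (0-1).
#' @param element_sd_nm Intrinsic Gaussian width (SD, biological nm) of the
#'   wall material before PSF blurring (default 8).
#' @return An object of class `centriole_spec`.
#' @export
centriole_spec <- function(view = c("top", "lateral"),
                           wall_radius_nm = 110, n_triplets = 9L,
                           tubulin_length_nm = c(450, 0),
                           protein_offset_nm = 0,
                           protein_coverage_frac = c(0.5, 0),
                           protein_position_frac = NA_real_,
                           ellipse_ratio = 1, break_arc_deg = 0,
                           break_start_deg = 0,
                           break_axial_range_frac = c(0, 1),
                           orientation_deg = 0, mod_depth = 0.6,
                           element_sd_nm = 8) {
  view <- match.arg(view)
  if (length(tubulin_length_nm) == 1L) tubulin_length_nm <- c(tubulin_length_nm, 0)
  if (length(protein_coverage_frac) == 1L) protein_coverage_frac <- c(protein_coverage_frac, 0)
  stopifnot(n_triplets >= 3L, wall_radius_nm > 0,
            protein_coverage_frac[1] >= 0, protein_coverage_frac[1] <= 1,
            ellipse_ratio > 0, ellipse_ratio <= 1,
            break_arc_deg >= 0, break_arc_deg < 360)
  if (!is.na(protein_position_frac)) {
    stopifnot(protein_position_frac >= 0, protein_position_frac <= 1,
              protein_position_frac + protein_coverage_frac[1] <= 1)
  }
  structure(list(view = view, wall_radius_nm = wall_radius_nm,
                 n_triplets = as.integer(n_triplets),
                 tubulin_length_nm = tubulin_length_nm,
                 protein_offset_nm = protein_offset_nm,
                 protein_coverage_frac = protein_coverage_frac,
                 protein_position_frac = protein_position_frac,
                 ellipse_ratio = ellipse_ratio,
                 break_arc_deg = break_arc_deg,
                 break_start_deg = break_start_deg,
                 break_axial_range_frac = break_axial_range_frac,
                 orientation_deg = orientation_deg,
                 mod_depth = mod_depth, element_sd_nm = element_sd_nm),
            class = "centriole_spec")
}

# Total rendered Gaussian SD in pixels: intrinsic element width plus PSF,
# both Gaussian, folded analytically.
render_sigma_px <- function(spec, imaging) {
  calib <- imaging$calib
  el <- spec$element_sd_nm * calib$x_factor / calib$pixel_nm
  psf <- (imaging$psf_fwhm_nm / (2 * sqrt(2 * log(2)))) / calib$pixel_nm
  sqrt(el^2 + psf^2)
}

# Accumulate isotropic Gaussian sources onto an [nx, ny] image via separable
# outer products (exact rendering of PSF-blurred point material).
render_gaussians <- function(nx, ny, xs, ys, amps, sigma) {
  img <- matrix(0, nx, ny)
  gx <- seq_len(nx); gy <- seq_len(ny)
  for (i in seq_along(xs)) {
    vx <- exp(-(gx - xs[i])^2 / (2 * sigma^2))
    vy <- exp(-(gy - ys[i])^2 / (2 * sigma^2))
    img <- img + amps[i] * (vx %o% vy)
  }
  img
}

# Apply Poisson + read noise to a noise-free channel (max-normalized).
apply_noise <- function(clean, imaging) {
  mx <- max(clean)
  scaled <- if (mx > 0) clean / mx * imaging$photon_scale else clean
  if (!imaging$noise) return(scaled)
  lambda <- scaled + imaging$background
  counts <- matrix(stats::rpois(length(lambda), as.vector(lambda)),
                   nrow(lambda), ncol(lambda))
  counts + matrix(stats::rnorm(length(lambda), 0, imaging$read_noise_sd),
                  nrow(lambda), ncol(lambda))
}

new_centriole_image <- function(channels, view, calib, meta = list()) {
  structure(list(channels = channels, view = view, calib = calib, meta = meta),
            class = "centriole_image")
}

#' @export
print.centriole_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("centriole_image (%s view): %d x %d px, channels: %s\n",
              x$view, d[1], d[2], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Render a synthetic top-view centriole
#'
#' The tubulin channel is a ring of dense wall material at the wall radius
#' (an ellipse when `ellipse_ratio < 1`) whose amplitude is modulated
#' nine-fold so individual triplets appear as angular intensity maxima; an
#' angular arc of wall is removed when `break_arc_deg > 0`. The protein
#' channel uses the same ring displaced radially inward by
#' `protein_offset_nm`. Both channels are blurred with the Gaussian PSF
#' (folded analytically into the rendering) and, unless `imaging$noise` is
#' `FALSE`, Poisson-sampled with read noise on top of a constant background.
#'
#' @param spec A [centriole_spec()] with `view = "top"`.
#' @param imaging An [imaging_spec()].
#' @param fov_px Optional square field of view in pixels; auto-sized to fit
#'   the ring plus 4 PSF sigmas when `NULL`. Too-small values error.
#' @return A list with `image` (a `centriole_image`, channels `tubulin` and
#'   `protein`) and `truth` (one-row data frame of ground-truth parameters).
#' @export
generate_top_view <- function(spec, imaging, fov_px = NULL) {
  stopifnot(inherits(spec, "centriole_spec"), spec$view == "top",
            inherits(imaging, "imaging_spec"))
  calib <- imaging$calib
  r_px <- biological_to_px(spec$wall_radius_nm, calib)
  sigma <- render_sigma_px(spec, imaging)
  need <- ceiling(2 * (r_px + 4 * sigma)) + 2
  if (is.null(fov_px)) fov_px <- need
  if (fov_px < 2 * (r_px + 3 * sigma)) {
    stop("geometry error: field of view too small for the ring")
  }
  nx <- ny <- as.integer(fov_px)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2

  phi <- spec$orientation_deg * pi / 180
  a <- r_px; b <- r_px * spec$ellipse_ratio
  step_deg <- max(0.25, min(1.5, 0.35 / r_px * 180 / pi))
  t_deg <- seq(0, 360 - step_deg, by = step_deg)
  # remove the broken arc (parametric angle, relative to orientation)
  if (spec$break_arc_deg > 0) {
    rel <- (t_deg - spec$break_start_deg) %% 360
    t_deg <- t_deg[rel >= spec$break_arc_deg]
  }
  t <- t_deg * pi / 180
  amp <- (1 + spec$mod_depth * cos(spec$n_triplets * t)) * step_deg
  ex <- a * cos(t); ey <- b * sin(t)
  xs <- cx + ex * cos(phi) - ey * sin(phi)
  ys <- cy + ex * sin(phi) + ey * cos(phi)
  tub <- render_gaussians(nx, ny, xs, ys, amp, sigma)

  off_px <- spec$protein_offset_nm * calib$x_factor / calib$pixel_nm
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  px <- cx + (xs - cx) * (1 - off_px / rr)
  py <- cy + (ys - cy) * (1 - off_px / rr)
  prot <- render_gaussians(nx, ny, px, py, amp, sigma)

  set.seed(imaging$seed)
  img <- new_centriole_image(
    list(tubulin = apply_noise(tub, imaging),
         protein = apply_noise(prot, imaging)),
    view = "top", calib = calib,
    meta = list(center_px = c(cx, cy)))
  truth <- data.frame(
    view = "top", wall_radius_nm = spec$wall_radius_nm,
    n_triplets = spec$n_triplets,
    true_delta_nm = spec$protein_offset_nm,
    true_roundness = spec$ellipse_ratio,
    break_arc_deg = spec$break_arc_deg,
    break_start_deg = spec$break_start_deg,
    broken = spec$break_arc_deg > 0,
    orientation_deg = spec$orientation_deg,
    tubulin_length_nm = NA_real_, protein_length_nm = NA_real_,
    coverage_pct = NA_real_, position_frac = NA_real_,
    seed = imaging$seed, stringsAsFactors = FALSE)
  list(image = img, truth = truth)
}

#' Render a synthetic lateral-view centriole
#'
#' The tubulin channel shows the two lateral walls of the barrel (separation
#' = wall diameter) over a length drawn from the configured truncated-normal
#' length distribution; the protein channel is a band covering
#' `protein_coverage_frac` of the tubulin length starting at
#' `protein_position_frac` (centred when `NA`), displaced inward by the
#' radial offset. The proximal end is at the low-axis end of the image
#' (before rotation by `orientation_deg`).
#'
#' @inheritParams generate_top_view
#' @param spec A [centriole_spec()] with `view = "lateral"`.
#' @return A list with `image` and `truth` as in [generate_top_view()];
#'   `truth` records the drawn tubulin/protein lengths and coverage.
#' @export
generate_lateral_view <- function(spec, imaging, fov_px = NULL) {
  stopifnot(inherits(spec, "centriole_spec"), spec$view == "lateral",
            inherits(imaging, "imaging_spec"))
  calib <- imaging$calib
  set.seed(imaging$seed)
  len_nm <- rtnorm(1, spec$tubulin_length_nm[1], spec$tubulin_length_nm[2],
                   lower = 4 * spec$element_sd_nm)
  cov <- min(1, rtnorm(1, spec$protein_coverage_frac[1],
                       spec$protein_coverage_frac[2], lower = 0.02))
  pos <- if (is.na(spec$protein_position_frac)) (1 - cov) / 2
         else min(spec$protein_position_frac, 1 - cov)

  r_px <- biological_to_px(spec$wall_radius_nm, calib)
  len_px <- biological_to_px(len_nm, calib)
  sigma <- render_sigma_px(spec, imaging)
  phi <- spec$orientation_deg * pi / 180
  half_u <- len_px / 2 + 4 * sigma
  half_v <- r_px + 4 * sigma
  # bounding box of the rotated barrel
  need_x <- 2 * (abs(half_u * cos(phi)) + abs(half_v * sin(phi))) + 2
  need_y <- 2 * (abs(half_u * sin(phi)) + abs(half_v * cos(phi))) + 2
  if (is.null(fov_px)) fov_px <- c(ceiling(need_x), ceiling(need_y))
  if (length(fov_px) == 1L) fov_px <- c(fov_px, fov_px)
  if (fov_px[1] < need_x - 2 || fov_px[2] < need_y - 2) {
    stop("geometry error: field of view too small for the barrel")
  }
  nx <- as.integer(fov_px[1]); ny <- as.integer(fov_px[2])
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2

  # wall lines as rows of dense sub-elements (u along axis, v transverse)
  du <- 0.35
  render_line <- function(u0, u1, v, weight = 1) {
    us <- seq(u0, u1, by = du)
    list(x = cx + us * cos(phi) - v * sin(phi),
         y = cy + us * sin(phi) + v * cos(phi),
         a = rep(weight * du, length(us)))
  }
  # lateral view through the barrel: both walls, minor-axis separation when
  # the cross-section is elliptical and viewed along the major axis
  vr <- r_px * spec$ellipse_ratio
  segs <- list(render_line(-len_px / 2, len_px / 2, -vr),
               render_line(-len_px / 2, len_px / 2, +vr))
  if (spec$break_arc_deg > 0) {
    # remove one wall over the configured axial interval (a lateral fracture)
    rng <- spec$break_axial_range_frac
    keep <- function(s) {
      u <- ((s$x - cx) * cos(phi) + (s$y - cy) * sin(phi)) / len_px + 0.5
      sel <- !(u >= rng[1] & u <= rng[2])
      list(x = s$x[sel], y = s$y[sel], a = s$a[sel])
    }
    segs[[2]] <- keep(segs[[2]])
  }
  xs <- unlist(lapply(segs, `[[`, "x")); ys <- unlist(lapply(segs, `[[`, "y"))
  as_ <- unlist(lapply(segs, `[[`, "a"))
  tub <- render_gaussians(nx, ny, xs, ys, as_, sigma)

  off_px <- spec$protein_offset_nm * calib$x_factor / calib$pixel_nm
  u0 <- (pos - 0.5) * len_px; u1 <- (pos + cov - 0.5) * len_px
  psegs <- list(render_line(u0, u1, -(vr - off_px)),
                render_line(u0, u1, +(vr - off_px)))
  pxs <- unlist(lapply(psegs, `[[`, "x")); pys <- unlist(lapply(psegs, `[[`, "y"))
  pas <- unlist(lapply(psegs, `[[`, "a"))
  prot <- render_gaussians(nx, ny, pxs, pys, pas, sigma)

  img <- new_centriole_image(
    list(tubulin = apply_noise(tub, imaging),
         protein = apply_noise(prot, imaging)),
    view = "lateral", calib = calib,
    meta = list(center_px = c(cx, cy), axis_deg = spec$orientation_deg))
  truth <- data.frame(
    view = "lateral", wall_radius_nm = spec$wall_radius_nm,
    n_triplets = spec$n_triplets,
    true_delta_nm = spec$protein_offset_nm,
    true_roundness = spec$ellipse_ratio,
    break_arc_deg = spec$break_arc_deg,
    break_start_deg = spec$break_start_deg,
    broken = spec$break_arc_deg > 0,
    orientation_deg = spec$orientation_deg,
    tubulin_length_nm = len_nm, protein_length_nm = cov * len_nm,
    coverage_pct = 100 * cov, position_frac = pos,
    seed = imaging$seed, stringsAsFactors = FALSE)
  list(image = img, truth = truth)
}

#' Render a multi-cell field of diffraction-limited foci
#'
#' Fixture for dot counting and intensity normalization: a grid of square
#' cell regions, each containing a drawn number of Gaussian foci per channel.
#' Cells in the "treated" half of the field have their focal peak intensity
#' scaled by `intensity_ratio`.
#'
#' @param n_cells Number of cells (>= 1).
#' @param foci_per_cell Either a single integer (same count per cell, channel
#'   1 only) or a named probability vector over joint `"a/b"` categories
#'   giving the channel-1/channel-2 counts per cell, e.g.
#'   `c("2/2" = 0.6, "2/4" = 0.4)`.
#' @param intensity_ratio Peak-intensity factor applied to treated cells.
#' @param imaging An [imaging_spec()].
#' @param cell_px Side of each square cell region in pixels (default 48).
#' @param n_treated Number of treated cells (default: half, rounded down;
#'   treated cells are the last `n_treated` cell ids).
#' @return A list with `image` (channels `ch1`, `ch2`), `cells` (integer
#'   label matrix of cell regions) and `truth` (per-cell data frame: counts
#'   per channel, group, intensity factor, category label).
#' @export
generate_cell_field <- function(n_cells, foci_per_cell = 2, intensity_ratio = 1,
                                imaging = imaging_spec(), cell_px = 48,
                                n_treated = if (intensity_ratio != 1) floor(n_cells / 2) else 0) {
  stopifnot(n_cells >= 1)
  set.seed(imaging$seed)
  sigma <- (imaging$psf_fwhm_nm / (2 * sqrt(2 * log(2)))) / imaging$calib$pixel_nm
  ngrid <- ceiling(sqrt(n_cells))
  nx <- ny <- ngrid * cell_px
  cells <- matrix(0L, nx, ny)
  draw_counts <- function() {
    if (is.numeric(foci_per_cell) && is.null(names(foci_per_cell))) {
      c(as.integer(foci_per_cell[1]), 0L)
    } else {
      cat_lab <- sample(names(foci_per_cell), 1L, prob = foci_per_cell)
      as.integer(strsplit(cat_lab, "/")[[1]])
    }
  }
  # foci on a jittered subgrid inside each cell: guarantees separation
  truth <- vector("list", n_cells)
  src <- list(ch1 = list(x = c(), y = c(), a = c()),
              ch2 = list(x = c(), y = c(), a = c()))
  margin <- ceiling(3 * sigma) + 2
  for (i in seq_len(n_cells)) {
    gx <- (i - 1) %% ngrid; gy <- (i - 1) %/% ngrid
    x0 <- gx * cell_px; y0 <- gy * cell_px
    cells[(x0 + 1):(x0 + cell_px), (y0 + 1):(y0 + cell_px)] <- i
    cnt <- draw_counts()
    sub <- max(3L, ceiling(sqrt(sum(cnt))))
    pitch <- (cell_px - 2 * margin) / sub
    if (pitch < 4 * sigma) {
      stop("packing error: too many foci for the cell area")
    }
    slots_per_cell <- sub * sub
    slot_xy <- expand.grid(ix = seq_len(sub) - 0.5, iy = seq_len(sub) - 0.5)
    slots <- slot_xy[sample.int(slots_per_cell, sum(cnt)), , drop = FALSE]
    jit <- pitch * 0.2
    fx <- x0 + margin + slots$ix * pitch + stats::runif(sum(cnt), -jit, jit)
    fy <- y0 + margin + slots$iy * pitch + stats::runif(sum(cnt), -jit, jit)
    treated <- i > (n_cells - n_treated)
    fac <- if (treated) intensity_ratio else 1
    ch <- rep(c(1L, 2L), cnt)
    for (k in seq_along(ch)) {
      key <- paste0("ch", ch[k])
      src[[key]]$x <- c(src[[key]]$x, fx[k])
      src[[key]]$y <- c(src[[key]]$y, fy[k])
      src[[key]]$a <- c(src[[key]]$a, fac)
    }
    truth[[i]] <- data.frame(cell_id = i, count_ch1 = cnt[1], count_ch2 = cnt[2],
                             category = paste(cnt[1], cnt[2], sep = "/"),
                             group = if (treated) "treated" else "control",
                             intensity_factor = fac, stringsAsFactors = FALSE)
  }
  render <- function(s) {
    if (!length(s$x)) return(matrix(0, nx, ny))
    render_gaussians(nx, ny, s$x, s$y, s$a, sigma)
  }
  clean <- list(ch1 = render(src$ch1), ch2 = render(src$ch2))
  # common photon scaling so the control/treated intensity ratio is preserved
  scale_common <- function(m, mx) {
    sc <- if (mx > 0) m / mx * imaging$photon_scale else m
    if (!imaging$noise) return(sc)
    lam <- sc + imaging$background
    matrix(stats::rpois(length(lam), as.vector(lam)), nx, ny) +
      matrix(stats::rnorm(length(lam), 0, imaging$read_noise_sd), nx, ny)
  }
  mx <- max(max(clean$ch1), max(clean$ch2), 1e-12)
  img <- new_centriole_image(
    list(ch1 = scale_common(clean$ch1, mx), ch2 = scale_common(clean$ch2, mx)),
    view = "field", calib = imaging$calib)
  list(image = img, cells = cells, truth = do.call(rbind, truth))
}

#' Specification of a decorated-microtubule line profile
#'
#' @param period_nm Repeat distance of decoration bumps (nm).
#' @param n_repeats Number of repeats.
#' @param bump_fwhm_nm FWHM of each Gaussian bump (default 4 nm).
#' @param noise_sd Additive Gaussian noise SD relative to bump amplitude 1.
#' @param sample_step_nm Sampling step; must be at most `period_nm / 4`.
#' @param seed Integer seed.
#' @return An object of class `decoration_profile_spec`.
#' @export
decoration_profile_spec <- function(period_nm, n_repeats, bump_fwhm_nm = 4,
                                    noise_sd = 0.1, sample_step_nm = 0.5,
                                    seed = 1L) {
  stopifnot(period_nm > 0, n_repeats >= 1, bump_fwhm_nm > 0, noise_sd >= 0)
  if (sample_step_nm > period_nm / 4) {
    stop("sample_step_nm must be at most period_nm / 4")
  }
  structure(list(period_nm = period_nm, n_repeats = as.integer(n_repeats),
                 bump_fwhm_nm = bump_fwhm_nm, noise_sd = noise_sd,
                 sample_step_nm = sample_step_nm, seed = as.integer(seed)),
            class = "decoration_profile_spec")
}

#' Generate a decorated-microtubule intensity profile
#'
#' Sum of Gaussian bumps centred every `period_nm` over `n_repeats` repeats,
#' plus additive Gaussian noise.
#'
#' @param spec A [decoration_profile_spec()].
#' @return A list with `profile` (data frame: `position_nm`, `intensity`) and
#'   `truth` (one-row data frame recording the true period and parameters).
#' @export
generate_decoration_profile <- function(spec) {
  stopifnot(inherits(spec, "decoration_profile_spec"))
  set.seed(spec$seed)
  margin <- 3 * spec$period_nm
  len <- (spec$n_repeats - 1) * spec$period_nm + 2 * margin
  pos <- seq(0, len, by = spec$sample_step_nm)
  centers <- margin + (seq_len(spec$n_repeats) - 1) * spec$period_nm
  sd_b <- spec$bump_fwhm_nm / (2 * sqrt(2 * log(2)))
  intensity <- rowSums(vapply(centers, function(c0)
    exp(-(pos - c0)^2 / (2 * sd_b^2)), numeric(length(pos))))
  if (spec$noise_sd > 0) {
    intensity <- intensity + stats::rnorm(length(pos), 0, spec$noise_sd)
  }
  list(profile = data.frame(position_nm = pos, intensity = intensity),
       truth = data.frame(period_nm = spec$period_nm,
                          n_repeats = spec$n_repeats,
                          bump_fwhm_nm = spec$bump_fwhm_nm,
                          noise_sd = spec$noise_sd,
                          sample_step_nm = spec$sample_step_nm,
                          seed = spec$seed))
}
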