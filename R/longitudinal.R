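# Lateral-view measurements: axial intensity profiles, FWHM-style signal
# lengths, coverage/positioning, and wall-to-wall diameter per region.

#' Axial intensity profile of a lateral-view centriole
#'
#' The centriole axis is the principal (second-moment) direction of the
#' thresholded tubulin channel. Intensities of every channel are averaged
#' across the transverse extent of the tubulin mask and sampled along the
#' axis every 0.5 px. Positions are reported in biological nm, increasing
#' from the proximal end; by default the proximal end is oriented so that
#' the protein band midpoint lies below the tubulin midpoint (the inner
#' scaffold sits above the proximal region), overridable via `proximal_end`.
#'
#' @param image A `centriole_image` (lateral view).
#' @param proximal_end `"auto"` (protein-band rule), `"low"` or `"high"`
#'   (keep / flip the raw axis direction).
#' @param calib Optional calibration override.
#' @return An object of class `axial_profile`: list with `positions_nm`,
#'   `channels` (named list of intensity vectors) and a `frame` describing
#'   the axis geometry (used by [measure_diameter()]).
#' @export
axial_profile <- function(image, proximal_end = c("auto", "low", "high"),
                          calib = NULL) {
  proximal_end <- match.arg(proximal_end)
  calib <- image_calib(image, calib)
  tub <- get_channel(image, "tubulin")
  bg <- stats::median(tub); mx <- max(tub)
  if (mx <= bg) stop("no signal in tubulin channel")
  w <- pmax(tub - (bg + 0.2 * (mx - bg)), 0)
  idx <- which(w > 0, arr.ind = TRUE)
  ww <- w[idx]
  cx <- sum(idx[, 1] * ww) / sum(ww); cy <- sum(idx[, 2] * ww) / sum(ww)
  dx <- idx[, 1] - cx; dy <- idx[, 2] - cy
  # Axis estimation. Second-moment PCA is unreliable here: the two wall
  # lines inflate the transverse variance, and near barrel lengths where
  # both moments coincide the eigenvectors rotate freely. Instead, the
  # transverse direction is the one whose intensity projection is maximally
  # bimodal (two wall lines -> minimal weighted kurtosis); it is found by a
  # coarse angular scan plus local refinement, and the axis is orthogonal.
  proj_kurtosis <- function(theta) {
    p <- dx * cos(theta) + dy * sin(theta)
    mu <- sum(ww * p) / sum(ww)
    s2 <- sum(ww * (p - mu)^2) / sum(ww)
    sum(ww * (p - mu)^4) / sum(ww) / s2^2
  }
  grid <- seq(0, pi, length.out = 91)[-91]
  kv <- vapply(grid, proj_kurtosis, numeric(1))
  if (diff(range(kv)) < 0.05) {
    stop("ambiguous axis: tubulin mask is not elongated")
  }
  th0 <- grid[which.min(kv)]
  opt <- stats::optimize(proj_kurtosis, interval = th0 + c(-0.05, 0.05) * pi)
  th_perp <- opt$minimum
  e2 <- c(cos(th_perp), sin(th_perp))     # transverse (wall-to-wall)
  e1 <- c(-e2[2], e2[1])                  # centriole axis
  u <- dx * e1[1] + dy * e1[2]
  v <- dx * e2[1] + dy * e2[2]
  pad <- 6
  ugrid <- seq(min(u) - pad, max(u) + pad, by = 0.5)
  vmax <- max(abs(v)) + 2
  vgrid <- seq(-vmax, vmax, by = 0.5)
  chans <- image$channels
  prof <- lapply(chans, function(m) {
    vapply(ugrid, function(ui) {
      mean(bilinear(m, cx + ui * e1[1] + vgrid * e2[1],
                    cy + ui * e1[2] + vgrid * e2[2]))
    }, numeric(1))
  })
  flip <- FALSE
  if (proximal_end == "high") flip <- TRUE
  if (proximal_end == "auto" && "protein" %in% names(prof)) {
    p <- prof$protein - min(prof$protein)
    t_ <- prof$tubulin - min(prof$tubulin)
    if (sum(p) > 0 && sum(t_) > 0) {
      flip <- sum(p * ugrid) / sum(p) > sum(t_ * ugrid) / sum(t_)
    }
  }
  if (flip) {
    prof <- lapply(prof, rev)
    ugrid <- rev(ugrid)
  }
  positions_nm <- to_biological_nm(seq_along(ugrid) * 0.5 - 0.5, calib)
  structure(list(positions_nm = positions_nm, channels = prof,
                 frame = list(center_px = c(cx, cy), e1 = e1, e2 = e2,
                              u_px = ugrid, vmax_px = vmax, flipped = flip)),
            class = "axial_profile", calib = calib)
}

#' Signal length along the axial profile
#'
#' Length between the outermost crossings of
#' `background + threshold_fraction * (max - background)` with linear
#' interpolation of the crossing positions (half maximum by default). The
#' background is the median of the profile's outer tails.
#'
#' @param profile An [axial_profile()].
#' @param channel Channel name (default `"tubulin"`).
#' @param threshold_fraction Fraction of the background-subtracted maximum
#'   (default 0.5).
#' @return A list of class `length_measurement`: `channel`, `length_nm`,
#'   `start_nm`, `end_nm`, `threshold_fraction`.
#' @export
measure_length <- function(profile, channel = "tubulin",
                           threshold_fraction = 0.5) {
  stopifnot(inherits(profile, "axial_profile"))
  y <- profile$channels[[channel]]
  if (is.null(y)) stop("profile has no channel '", channel, "'")
  pos <- profile$positions_nm
  k <- max(3L, round(length(y) * 0.05))
  bg <- stats::median(c(utils::head(y, k), utils::tail(y, k)))
  mx <- max(y)
  if (mx <= bg) stop("no signal: profile never exceeds background")
  level <- bg + threshold_fraction * (mx - bg)
  cr <- outer_crossings(pos, y, level)
  if (is.null(cr)) stop("no signal: profile never exceeds threshold")
  structure(list(channel = channel, length_nm = cr[2] - cr[1],
                 start_nm = cr[1], end_nm = cr[2],
                 threshold_fraction = threshold_fraction),
            class = "length_measurement")
}

#' Coverage and axial positioning of a protein band
#'
#' @param tub Tubulin [measure_length()] result.
#' @param prot Protein-band [measure_length()] result from the same profile.
#' @return A list of class `coverage_result`: `tubulin_length_nm`,
#'   `protein_length_nm`, `coverage_pct` (100 * protein/tubulin) and
#'   `position_pct` (band midpoint as % of the tubulin extent from the
#'   proximal end).
#' @export
coverage_and_position <- function(tub, prot) {
  stopifnot(inherits(tub, "length_measurement"),
            inherits(prot, "length_measurement"))
  if (tub$length_nm <= 0) stop("division error: tubulin length is zero")
  mid <- (prot$start_nm + prot$end_nm) / 2
  structure(list(tubulin_length_nm = tub$length_nm,
                 protein_length_nm = prot$length_nm,
                 coverage_pct = 100 * prot$length_nm / tub$length_nm,
                 position_pct = 100 * (mid - tub$start_nm) / tub$length_nm),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("Coverage: %.0f%% (protein %.0f / tubulin %.0f nm), midpoint at %.0f%%\n",
              x$coverage_pct, x$protein_length_nm, x$tubulin_length_nm,
              x$position_pct))
  invisible(x)
}

#' Define proximal / core / distal measurement regions
#'
#' Control rule: the proximal region is the axial interval below the inner
#' scaffold band, the core is the band interval, and the distal region lies
#' above it. Depleted rule (reduced proximal belt): the proximal region lies
#' below the remaining belt, the core is measured just above the belt, and
#' the distal region is the last 100 nm of the centriole.
#'
#' @param tub Tubulin [measure_length()] result.
#' @param prot Protein-band [measure_length()] result, or `NULL`.
#' @param depleted Apply the depleted-condition rule.
#' @param distal_nm Distal-region extent for the depleted rule (100 nm).
#' @param core_gap_nm Half-width of the core scan interval above the belt
#'   for the depleted rule (default 50 nm).
#' @return Data frame with columns `region`, `start_nm`, `end_nm`,
#'   `position_nm` (representative scan position = interval midpoint).
#' @export
define_regions <- function(tub, prot = NULL, depleted = FALSE,
                           distal_nm = 100, core_gap_nm = 50) {
  stopifnot(inherits(tub, "length_measurement"))
  if (is.null(prot) && !depleted) {
    stop("cannot define regions: no protein band and depleted = FALSE")
  }
  eps <- 1e-6
  if (!depleted) {
    if (prot$start_nm <= tub$start_nm + eps && prot$end_nm >= tub$end_nm - eps) {
      stop("cannot define regions: band covers the full tubulin extent")
    }
    iv <- rbind(c(tub$start_nm, prot$start_nm),
                c(prot$start_nm, prot$end_nm),
                c(prot$end_nm, tub$end_nm))
  } else {
    belt_end <- if (is.null(prot)) tub$start_nm else prot$end_nm
    core_hi <- min(belt_end + 2 * core_gap_nm, tub$end_nm - distal_nm)
    iv <- rbind(c(tub$start_nm, if (is.null(prot)) tub$start_nm + distal_nm else prot$start_nm),
                c(belt_end, core_hi),
                c(tub$end_nm - distal_nm, tub$end_nm))
  }
  if (any(iv[, 2] <= iv[, 1])) {
    stop("cannot define regions: degenerate region interval")
  }
  data.frame(region = c("proximal", "core", "distal"),
             start_nm = iv[, 1], end_nm = iv[, 2],
             position_nm = rowMeans(iv), stringsAsFactors = FALSE)
}

#' Wall-to-wall diameter at a region of a lateral view
#'
#' Averages the transverse intensity profile over a band of `band_px`
#' thickness perpendicular to the centriole axis at the region's
#' representative axial position, and reports the subpixel-refined distance
#' between the two outermost transverse peaks (the two wall lines) in
#' biological nm.
#'
#' @param image A `centriole_image` (lateral view).
#' @param profile The [axial_profile()] of the same image (supplies the axis
#'   frame).
#' @param region_rules Data frame from [define_regions()].
#' @param region `"proximal"`, `"core"` or `"distal"`.
#' @param band_px Band thickness along the axis in pixels (default 50).
#' @param channel Channel to measure (default `"tubulin"`).
#' @return A list of class `diameter_result`: `region`, `diameter_nm`,
#'   `axial_position_nm`.
#' @export
measure_diameter <- function(image, profile, region_rules, region,
                             band_px = 50, channel = "tubulin") {
  stopifnot(inherits(profile, "axial_profile"))
  calib <- attr(profile, "calib")
  rr <- region_rules[region_rules$region == region, ]
  if (!nrow(rr)) stop("unknown region '", region, "'")
  fr <- profile$frame
  m <- get_channel(image, channel)
  # axial position (nm) -> u (px) through the recorded grid
  u0 <- stats::approx(profile$positions_nm, fr$u_px, rr$position_nm,
                      rule = 2)$y
  # clamp the scan band to the region interval
  half_nm <- to_biological_nm(band_px / 2, calib)
  lo_nm <- max(rr$start_nm, rr$position_nm - half_nm)
  hi_nm <- min(rr$end_nm, rr$position_nm + half_nm)
  us <- stats::approx(profile$positions_nm, fr$u_px,
                      seq(lo_nm, hi_nm, length.out = max(5, band_px)),
                      rule = 2)$y
  vgrid <- seq(-fr$vmax_px, fr$vmax_px, by = 0.25)
  tv <- vapply(vgrid, function(vi) {
    mean(bilinear(m, fr$center_px[1] + us * fr$e1[1] + vi * fr$e2[1],
                  fr$center_px[2] + us * fr$e1[2] + vi * fr$e2[2]))
  }, numeric(1))
  bg <- stats::median(tv[tv <= stats::quantile(tv, 0.3)])
  pk <- find_local_maxima(tv, min_prominence = 0.15 * (max(tv) - bg),
                          min_separation = 4L)
  if (length(pk) < 2) stop("unresolved wall: fewer than two transverse peaks")
  j1 <- refine_peak(tv, pk[1]); j2 <- refine_peak(tv, pk[length(pk)])
  d_px <- (j2 - j1) * 0.25
  structure(list(region = region,
                 diameter_nm = to_biological_nm(d_px, calib),
                 axial_position_nm = rr$position_nm),
            class = "diameter_result")
}
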