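# Top-view shape descriptors: wall-peak detection, ellipse-fit roundness,
# and broken-wall (fracture) assessment from the angular wall trace.

#' Detect tubulin wall peaks around a top-view ring
#'
#' The wall is unrolled into an angular intensity trace (max over radius per
#' 1-degree sector, circularly smoothed); local maxima with prominence of at
#' least `min_prominence` of the trace maximum and an angular separation of
#' at least `min_separation_deg` are the triplet peaks. Each peak's radial
#' position is refined by quadratic subpixel interpolation.
#'
#' @param image A `centriole_image` (top view) or tubulin matrix.
#' @param center Ring centre from [find_center()].
#' @param min_prominence Prominence threshold, fraction of trace max (0.2).
#' @param min_separation_deg Minimum angular separation between peaks (20).
#' @param calib Optional calibration override.
#' @return An object of class `wall_peaks`: data frame with `angle_deg`,
#'   `radius_px`, `radius_nm`, `x_px`, `y_px`, `intensity`; attributes
#'   `center` and `calib`.
#' @export
detect_wall_peaks <- function(image, center, min_prominence = 0.2,
                              min_separation_deg = 20, calib = NULL) {
  calib <- image_calib(image, calib)
  m <- get_channel(image, "tubulin")
  tr <- angular_wall_trace(m, center, step_deg = 1)
  sm <- circular_smooth(tr$intensity, 7L)
  pk <- find_local_maxima(sm, min_prominence = min_prominence * max(sm),
                          min_separation = as.integer(min_separation_deg),
                          circular = TRUE)
  if (length(pk) < 3) stop("insufficient peaks: fewer than 3 wall maxima")
  ang <- vapply(pk, function(i) {
    j <- refine_peak(sm, i)                 # subdegree angular refinement
    tr$angle_deg[1] + (j - 1)
  }, numeric(1))
  rad <- tr$peak_radius_px[pk]
  th <- ang * pi / 180
  out <- data.frame(angle_deg = ang %% 360, radius_px = rad,
                    radius_nm = to_biological_nm(rad, calib),
                    x_px = center[1] + rad * cos(th),
                    y_px = center[2] + rad * sin(th),
                    intensity = tr$intensity[pk])
  out <- out[order(out$angle_deg), ]
  rownames(out) <- NULL
  structure(out, class = c("wall_peaks", "data.frame"),
            center = center, calib = calib)
}

#' Wall ridge points of a top-view centriole
#'
#' Samples the radial wall-peak position in every 1-degree sector whose
#' signal exceeds `min_frac` of the angular trace maximum. Unlike
#' [detect_wall_peaks()] (which returns the nine triplet maxima) this gives
#' a dense point set along the wall ridge, keeping the ellipse fit
#' well-posed on strongly deformed centrioles whose triplet maxima merge
#' under the PSF.
#'
#' @inheritParams detect_wall_peaks
#' @param min_frac Sector admission threshold, fraction of trace max (0.3).
#' @return A `wall_peaks`-like data frame (one row per admitted sector).
#' @export
wall_ridge_points <- function(image, center, min_frac = 0.3, calib = NULL) {
  calib <- image_calib(image, calib)
  m <- get_channel(image, "tubulin")
  tr <- angular_wall_trace(m, center, step_deg = 1)
  sm <- circular_smooth(tr$intensity, 5L)
  keep <- sm >= min_frac * max(sm)
  th <- tr$angle_deg[keep] * pi / 180
  rad <- tr$peak_radius_px[keep]
  structure(data.frame(angle_deg = tr$angle_deg[keep], radius_px = rad,
                       radius_nm = to_biological_nm(rad, calib),
                       x_px = center[1] + rad * cos(th),
                       y_px = center[2] + rad * sin(th),
                       intensity = tr$intensity[keep]),
            class = c("wall_peaks", "data.frame"),
            center = center, calib = calib)
}

# Direct least-squares ellipse fit (Halir & Flusser's numerically stable
# variant of Fitzgibbon's method). Returns centre, semi-axes, orientation.
fit_ellipse <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)),
                 error = function(e) stop("degenerate fit: collinear points"))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # admissible solution: 4ac - b^2 > 0
  cond <- 4 * ev$vectors[1, ] * ev$vectors[3, ] - ev$vectors[2, ]^2
  idx <- which(Re(cond) > 0 & abs(Im(ev$values)) < 1e-8)
  if (!length(idx)) stop("degenerate fit: points do not define an ellipse")
  a1 <- Re(ev$vectors[, idx[1]])
  coef <- c(a1, T_ %*% a1)   # A B C D E F for centred data
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * ((A + C) + s)) / den
  ax2 <- -sqrt(num * ((A + C) - s)) / den
  semi <- sort(c(ax1, ax2), decreasing = TRUE)
  theta <- 0.5 * atan2(B, A - C)
  list(center = c(cx + mx, cy + my), major = semi[1], minor = semi[2],
       angle_rad = theta)
}

#' Roundness of a centriole from its wall peaks
#'
#' Fits an ellipse to the detected wall-peak points by direct least squares
#' and reports roundness = minor/major axis ratio (1 for a circle). The
#' polygon obtained by connecting the peaks in angular order is summarized
#' alongside (area, perimeter, circularity = 4*pi*area/perimeter^2). Views
#' whose wall-peak radial spread exceeds `tilt_max` of the mean radius are
#' flagged as inadmissible (oblique views mimic ellipticity).
#'
#' @param peaks A `wall_peaks` object (or a data frame with `x_px`, `y_px`),
#'   at least 5 points.
#' @param tilt_max Admission threshold on radial SD / mean radius (0.15).
#' @return A list of class `roundness_result`: `roundness`, `major_axis_nm`,
#'   `minor_axis_nm`, `polygon_area`, `polygon_perimeter`, `circularity`,
#'   `admissible`.
#' @export
compute_roundness <- function(peaks, tilt_max = 0.15) {
  x <- peaks$x_px; y <- peaks$y_px
  if (length(x) < 5) stop("ellipse fit needs at least 5 peaks")
  fit <- fit_ellipse(x, y)
  calib <- attr(peaks, "calib")
  to_nm <- function(v) if (is.null(calib)) v else to_biological_nm(v, calib)
  # polygon metrics in angular order about the fitted centre
  ang <- atan2(y - fit$center[2], x - fit$center[1])
  o <- order(ang)
  px <- x[o]; py <- y[o]
  j <- c(seq_along(px)[-1], 1L)
  area <- abs(sum(px * py[j] - px[j] * py)) / 2
  perim <- sum(sqrt((px[j] - px)^2 + (py[j] - py)^2))
  r <- sqrt((x - fit$center[1])^2 + (y - fit$center[2])^2)
  admissible <- stats::sd(r) / mean(r) < tilt_max
  structure(list(roundness = fit$minor / fit$major,
                 major_axis_nm = to_nm(2 * fit$major),
                 minor_axis_nm = to_nm(2 * fit$minor),
                 polygon_area = area, polygon_perimeter = perim,
                 circularity = 4 * pi * area / perim^2,
                 admissible = admissible),
            class = "roundness_result")
}

#' @export
print.roundness_result <- function(x, ...) {
  cat(sprintf("Roundness %.3f (axes %.0f x %.0f nm), circularity %.3f%s\n",
              x$roundness, x$major_axis_nm, x$minor_axis_nm, x$circularity,
              if (x$admissible) "" else " [inadmissible view]"))
  invisible(x)
}

#' Assess microtubule-wall integrity of a top view
#'
#' The wall signal per 1-degree sector is the max-over-radius intensity;
#' sectors below `missing_frac` of the trace maximum are "missing". The
#' largest contiguous missing arc is reported, with its boundaries refined
#' to the half-maximum crossings of the angular trace (unbiased edge
#' localization for a PSF-blurred wall end). The wall is flagged broken when
#' the arc exceeds `gap_threshold_deg`.
#'
#' @param image A `centriole_image` (top view) or tubulin matrix.
#' @param center Ring centre from [find_center()].
#' @param gap_threshold_deg Broken-wall threshold in degrees (default 45,
#'   i.e. more than one missing triplet).
#' @param missing_frac Missing-sector threshold, fraction of trace max (0.15).
#' @return A list of class `wall_integrity_result`: `broken`,
#'   `largest_gap_deg`, `gap_location_deg` (gap midpoint).
#' @export
assess_wall_integrity <- function(image, center, gap_threshold_deg = 45,
                                  missing_frac = 0.15) {
  m <- get_channel(image, "tubulin")
  tr <- angular_wall_trace(m, center, step_deg = 1)
  v <- circular_smooth(tr$intensity, 5L)
  bg <- stats::median(m)
  v <- pmax(v - bg, 0)
  mx <- max(v)
  if (mx <= 0) stop("no signal: empty image")
  miss <- v < missing_frac * mx
  n <- length(miss)
  if (!any(miss)) {
    return(structure(list(broken = FALSE, largest_gap_deg = 0,
                          gap_location_deg = NA_real_),
                     class = "wall_integrity_result"))
  }
  if (all(miss)) stop("no signal: wall absent in every sector")
  # largest circular run of missing sectors
  r <- rle(miss)
  runs <- data.frame(len = r$lengths, val = r$values,
                     start = cumsum(c(1, utils::head(r$lengths, -1))))
  if (r$values[1] && r$values[length(r$values)]) {  # wrap-around merge
    runs$len[nrow(runs)] <- runs$len[nrow(runs)] + runs$len[1]
    runs <- runs[-1, ]
  }
  gaps <- runs[runs$val, , drop = FALSE]
  gi <- gaps[which.max(gaps$len), ]
  # refine both boundaries to the half-max crossing of the trace
  half <- 0.5 * mx
  cross_out <- function(idx0, step) {
    i <- idx0
    for (k in seq_len(n)) {
      jn <- ((i + step - 1) %% n) + 1
      if (v[jn] >= half) {
        frac <- (half - v[i]) / (v[jn] - v[i])
        return(((i - 1) + step * frac) %% n)  # 0-based degrees
      }
      i <- jn
    }
    (idx0 - 1) %% n
  }
  lo <- cross_out(gi$start, -1L)
  hi <- cross_out(((gi$start + gi$len - 2) %% n) + 1, +1L)
  gap <- (hi - lo) %% n
  if (gap == 0) gap <- gi$len
  mid <- (lo + gap / 2) %% 360
  structure(list(broken = gap > gap_threshold_deg,
                 largest_gap_deg = gap, gap_location_deg = mid),
            class = "wall_integrity_result")
}

#' @export
print.wall_integrity_result <- function(x, ...) {
  cat(sprintf("Wall integrity: %s (largest gap %.0f deg)\n",
              if (x$broken) "BROKEN" else "intact", x$largest_gap_deg))
  invisible(x)
}
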