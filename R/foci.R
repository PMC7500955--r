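# Confocal-scale quantification: spot (focus) detection, per-cell dot
# counting, centrosomal/centriolar intensity, control normalization.

# Separable Gaussian blur with replicated edges (small kernels only).
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], r), x, rep(x[n], r))
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
  }
  m2 <- apply(m, 2, pad_conv)
  t(apply(t(m2), 2, pad_conv))
}

#' Detect diffraction-limited foci in a channel
#'
#' Band-pass filters the channel with a difference of Gaussians at the
#' diffraction scale, then keeps local maxima exceeding
#' `background + threshold_sd * SD` (robust background statistics from the
#' filtered image), non-maximum-suppressed at `min_separation_px`.
#'
#' @param image A `centriole_image` or bare matrix.
#' @param channel Channel name (ignored for a matrix).
#' @param threshold_sd Detection threshold in robust SDs (default 5).
#' @param min_separation_px Minimum separation between foci (default 5).
#' @param sigma_px Inner DoG scale in pixels (default 1.5; outer is 2x).
#' @return Data frame of foci: `x_px`, `y_px`, `peak_intensity` (from the
#'   unfiltered channel). Zero rows when nothing is detected.
#' @export
detect_foci <- function(image, channel = "ch1", threshold_sd = 5,
                        min_separation_px = 5, sigma_px = 1.5) {
  m <- get_channel(image, channel)
  bp <- gaussian_blur(m, sigma_px) - gaussian_blur(m, 2 * sigma_px)
  bg <- stats::median(bp)
  s <- stats::mad(bp)
  if (s == 0) s <- stats::sd(bp)
  thr <- bg + threshold_sd * s
  nx <- nrow(bp); ny <- ncol(bp)
  cand <- which(bp > thr, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      peak_intensity = numeric(0)))
  }
  # strict local maxima over the 8-neighbourhood
  is_max <- apply(cand, 1, function(p) {
    x <- p[1]; y <- p[2]
    nb <- expand.grid(dx = -1:1, dy = -1:1)
    nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
    xs <- pmin(pmax(x + nb$dx, 1), nx); ys <- pmin(pmax(y + nb$dy, 1), ny)
    all(bp[x, y] >= bp[cbind(xs, ys)])
  })
  cand <- cand[is_max, , drop = FALSE]
  vals <- bp[cand]
  o <- order(vals, decreasing = TRUE)
  sel <- matrix(numeric(0), 0, 2)
  for (i in o) {
    p <- cand[i, ]
    if (!nrow(sel) ||
        all((sel[, 1] - p[1])^2 + (sel[, 2] - p[2])^2 >= min_separation_px^2)) {
      sel <- rbind(sel, p)
    }
  }
  data.frame(x_px = sel[, 1], y_px = sel[, 2],
             peak_intensity = m[sel, drop = FALSE])
}

#' Count foci per cell and tabulate joint categories
#'
#' @param foci_by_channel Named list of foci data frames (one per channel)
#'   from [detect_foci()].
#' @param cells Integer label matrix of cell regions (0 = outside).
#' @return A list with `counts` (data frame: `cell_id`, one `count_*` column
#'   per channel, `category` joining the counts as `"a/b"`) and
#'   `category_pct` (data frame: `category`, `percent`). Foci outside every
#'   region are dropped (and counted in attribute `"n_dropped"`).
#' @export
count_dots_per_cell <- function(foci_by_channel, cells) {
  ids <- sort(unique(cells[cells > 0]))
  dropped <- 0L
  counts <- lapply(foci_by_channel, function(f) {
    tab <- setNames(integer(length(ids)), ids)
    if (nrow(f)) {
      lab <- cells[cbind(round(f$x_px), round(f$y_px))]
      dropped <<- dropped + sum(lab == 0)
      t2 <- table(lab[lab > 0])
      tab[names(t2)] <- as.integer(t2)
    }
    tab
  })
  df <- data.frame(cell_id = ids)
  for (nm in names(counts)) df[[paste0("count_", nm)]] <- as.integer(counts[[nm]])
  df$category <- do.call(paste, c(counts, sep = "/"))
  tab <- table(df$category)
  pct <- data.frame(category = names(tab),
                    percent = 100 * as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  structure(list(counts = df, category_pct = pct), n_dropped = dropped)
}

disc_offsets <- function(area_px) {
  r <- sqrt(area_px / pi)
  g <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  g <- g[g$dx^2 + g$dy^2 <= r^2, ]
  # trim/pad to exactly area_px pixels, nearest-first
  g <- g[order(g$dx^2 + g$dy^2), ]
  if (nrow(g) > area_px) g <- g[seq_len(area_px), ]
  g
}

#' Integrated centrosomal intensity over a fixed-area region
#'
#' Sums the background-subtracted intensity over a region of `area_px`
#' pixels centred on the centrosome: a disc by default, or a square box
#' (side `sqrt(area_px)`, rounded) when `shape = "box"`.
#'
#' @param image A `centriole_image` or matrix.
#' @param center Centre `(x, y)` in pixels.
#' @param channel Channel name.
#' @param area_px Region area in pixels (default 20).
#' @param shape `"disc"` or `"box"`.
#' @param background Background level per pixel; default: channel median.
#' @return Raw integrated intensity (numeric).
#' @export
centrosomal_intensity <- function(image, center, channel = "ch1",
                                  area_px = 20, shape = c("disc", "box"),
                                  background = NULL) {
  shape <- match.arg(shape)
  m <- get_channel(image, channel)
  if (is.null(background)) background <- stats::median(m)
  offs <- if (shape == "disc") {
    disc_offsets(area_px)
  } else {
    side <- round(sqrt(area_px))
    h <- (side - 1) / 2
    expand.grid(dx = round(-h:h), dy = round(-h:h))
  }
  xs <- round(center[1]) + offs$dx; ys <- round(center[2]) + offs$dy
  if (any(xs < 1 | xs > nrow(m) | ys < 1 | ys > ncol(m))) {
    stop("partial region: measurement area clipped by the image border")
  }
  sum(m[cbind(xs, ys)] - background)
}

#' Mean centriolar intensity along a line profile
#'
#' Mean of an `n_points` interpolated intensity profile along a segment,
#' background-subtracted.
#'
#' @param image A `centriole_image` or matrix.
#' @param p0,p1 Segment endpoints `(x, y)` in pixels.
#' @param channel Channel name.
#' @param n_points Number of profile points (default 25).
#' @param background Background per pixel; default: channel median.
#' @return Mean background-subtracted intensity (numeric).
#' @export
centriolar_profile_intensity <- function(image, p0, p1, channel = "ch1",
                                         n_points = 25, background = NULL) {
  m <- get_channel(image, channel)
  if (is.null(background)) background <- stats::median(m)
  t_ <- seq(0, 1, length.out = n_points)
  xs <- p0[1] + t_ * (p1[1] - p0[1]); ys <- p0[2] + t_ * (p1[2] - p0[2])
  if (any(xs < 1 | xs > nrow(m) | ys < 1 | ys > ncol(m))) {
    stop("partial region: profile leaves the image")
  }
  mean(bilinear(m, xs, ys)) - background
}

#' Normalize intensities to the control-group mean
#'
#' Each value is divided by the mean of the control values, yielding
#' relative intensities (A.U.) whose control-group mean is 1 by
#' construction.
#'
#' @param values Numeric vector of raw measurements.
#' @param control_values Numeric vector of control-group raw measurements.
#' @return Data frame with `raw` and `relative_au`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (!length(control_values)) stop("normalization error: empty control group")
  m <- mean(control_values)
  if (m == 0) stop("normalization error: zero control mean")
  data.frame(raw = values, relative_au = values / m)
}
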