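# Top-view radial mapping: locate the ring centre, cast radial spokes at the
# triplet positions, and measure the tubulin-to-protein peak offset per spoke.

get_channel <- function(image, channel) {
  if (is.matrix(image)) return(image)
  stopifnot(inherits(image, "centriole_image"))
  m <- image$channels[[channel]]
  if (is.null(m)) stop("image has no channel '", channel, "'")
  m
}

image_calib <- function(image, calib = NULL) {
  if (!is.null(calib)) return(calib)
  if (inherits(image, "centriole_image")) return(image$calib)
  stop("a calibration is required when passing a bare matrix")
}

# Angular trace of the wall about `center`: per `step_deg` sector, the
# max-over-radius intensity along the central ray and the radius at which it
# occurs. Radii sampled at 0.5 px with bilinear interpolation.
angular_wall_trace <- function(m, center, step_deg = 1, r_max = NULL) {
  nx <- nrow(m); ny <- ncol(m)
  if (center[1] < 1 || center[1] > nx || center[2] < 1 || center[2] > ny) {
    stop("geometry error: center outside image")
  }
  if (is.null(r_max)) {
    r_max <- min(center[1] - 1, nx - center[1], center[2] - 1, ny - center[2])
  }
  radii <- seq(0.5, r_max, by = 0.5)
  angles <- seq(0, 360 - step_deg, by = step_deg)
  th <- angles * pi / 180
  vals <- numeric(length(angles)); rpk <- numeric(length(angles))
  for (i in seq_along(angles)) {
    prof <- bilinear(m, center[1] + radii * cos(th[i]),
                     center[2] + radii * sin(th[i]))
    j <- which.max(prof)
    vals[i] <- prof[j]
    rpk[i] <- 0.5 * refine_peak(prof, j)  # radii grid is 0.5 px, offset 0.5
  }
  list(angle_deg = angles, intensity = vals, peak_radius_px = rpk)
}

#' Locate the centre of a top-view centriole ring
#'
#' Starting from the intensity centroid of the thresholded tubulin channel,
#' the centre is refined by minimizing the angular variance of the wall-peak
#' radius (a centred ring has the same peak radius in every direction).
#'
#' @param image A `centriole_image` (top view) or a bare tubulin matrix.
#' @param channel Channel used for centring (default `"tubulin"`).
#' @param refine Run the angular-uniformity refinement (default `TRUE`).
#' @return Numeric length-2 centre `(x, y)` in pixels.
#' @export
find_center <- function(image, channel = "tubulin", refine = TRUE) {
  m <- get_channel(image, channel)
  bg <- stats::median(m)
  mx <- max(m)
  if (mx <= bg) stop("empty image: no above-threshold signal")
  w <- pmax(m - (bg + 0.3 * (mx - bg)), 0)
  if (sum(w) == 0) stop("empty image: no above-threshold signal")
  gx <- seq_len(nrow(m)); gy <- seq_len(ncol(m))
  c0 <- c(sum(rowSums(w) * gx), sum(colSums(w) * gy)) / sum(w)
  if (!refine) return(c0)
  cost <- function(p) {
    if (p[1] < 2 || p[1] > nrow(m) - 1 || p[2] < 2 || p[2] > ncol(m) - 1) {
      return(1e9)
    }
    tr <- angular_wall_trace(m, p, step_deg = 10)
    keep <- tr$intensity > bg + 0.3 * (mx - bg)
    if (sum(keep) < 4) return(1e9)
    stats::var(tr$peak_radius_px[keep])
  }
  fit <- stats::optim(c0, cost, method = "Nelder-Mead",
                      control = list(reltol = 1e-6, maxit = 200))
  fit$par
}

#' Extract radial spoke profiles from a top view
#'
#' Spokes are cast at the angular maxima of the tubulin wall (the triplet
#' positions), or at explicitly supplied angles. Each spoke is the radial
#' intensity profile averaged over a small angular wedge, sampled every
#' 0.5 px with bilinear interpolation; radii are reported in biological nm.
#'
#' @param image A `centriole_image` (top view).
#' @param center Ring centre from [find_center()].
#' @param n_spokes Number of spokes to cast (default: detected triplet
#'   angles, at most this many).
#' @param wedge_deg Angular wedge over which each spoke averages (default 8).
#' @param angles_deg Optional explicit spoke angles (overrides detection).
#' @param calib Optional calibration override.
#' @return A list of spoke profiles, each a list with `angle_deg`,
#'   `radii_nm` (increasing, centre outward: interior to exterior) and one
#'   intensity vector per channel; class `spoke_set`.
#' @export
extract_spokes <- function(image, center, n_spokes = 9L, wedge_deg = 8,
                           angles_deg = NULL, calib = NULL) {
  calib <- image_calib(image, calib)
  tub <- get_channel(image, "tubulin")
  if (wedge_deg >= 360 / n_spokes) {
    stop("wedge_deg must be smaller than the spoke spacing")
  }
  if (is.null(angles_deg)) {
    tr <- angular_wall_trace(tub, center, step_deg = 1)
    sm <- circular_smooth(tr$intensity, 7L)
    pk <- find_local_maxima(sm, min_prominence = 0.1 * max(sm),
                            min_separation = 20L, circular = TRUE)
    if (!length(pk)) stop("no wall maxima found for spoke casting")
    if (length(pk) > n_spokes) {
      pk <- sort(pk[order(sm[pk], decreasing = TRUE)][seq_len(n_spokes)])
    }
    angles_deg <- tr$angle_deg[pk]
  }
  nx <- nrow(tub); ny <- ncol(tub)
  r_max <- min(center[1] - 1, nx - center[1], center[2] - 1, ny - center[2])
  radii_px <- seq(0.5, r_max, by = 0.5)
  sub <- seq(-wedge_deg / 2, wedge_deg / 2, length.out = 5)
  chans <- if (is.matrix(image)) list(tubulin = image) else image$channels
  spokes <- lapply(angles_deg, function(a) {
    th <- (a + sub) * pi / 180
    prof <- lapply(chans, function(m) {
      acc <- 0
      for (t in th) {
        acc <- acc + bilinear(m, center[1] + radii_px * cos(t),
                              center[2] + radii_px * sin(t))
      }
      acc / length(th)
    })
    c(list(angle_deg = a, radii_nm = to_biological_nm(radii_px, calib)),
      prof)
  })
  structure(spokes, class = "spoke_set", calib = calib)
}

#' Measure per-triplet radial offsets between tubulin and protein peaks
#'
#' For each spoke the tubulin peak radius is located by 3-point quadratic
#' (subpixel) interpolation around the discrete maximum; the protein peak is
#' searched within `window_nm` of the tubulin peak with the same refinement.
#' A spoke is marked unresolved when either peak's amplitude above the local
#' baseline falls below `min_prominence` of the channel's maximal spoke
#' amplitude. The offset is `delta_nm = r_tubulin - r_protein`, positive when
#' the protein sits interior to the wall (toward the lumen).
#'
#' @param spokes A `spoke_set` from [extract_spokes()].
#' @param window_nm Half-width of the protein search window in biological nm
#'   (default 60).
#' @param min_prominence Resolution threshold as a fraction of the channel
#'   maximum (default 0.2).
#' @param protein Name of the protein channel (default `"protein"`).
#' @return An object of class `radial_map_result`: list with `offsets` (data
#'   frame: `triplet_index`, `angle_deg`, `r_tubulin_nm`, `r_protein_nm`,
#'   `delta_nm`, `resolved`), `mean_delta_nm`, `sd_delta_nm`,
#'   `n_measurements`.
#' @export
measure_triplet_offsets <- function(spokes, window_nm = 60,
                                    min_prominence = 0.2,
                                    protein = "protein") {
  stopifnot(inherits(spokes, "spoke_set"))
  peak_in <- function(radii, prof, lo, hi) {
    sel <- which(radii >= lo & radii <= hi)
    if (length(sel) < 3) return(NULL)
    j <- sel[which.max(prof[sel])]
    jr <- refine_peak(prof, j)
    step <- radii[2] - radii[1]
    list(r = radii[1] + (jr - 1) * step, value = prof[j])
  }
  base <- function(prof) stats::median(prof[prof <= stats::quantile(prof, 0.4)])
  tub_max <- max(vapply(spokes, function(s) max(s$tubulin), numeric(1)))
  prot_max <- max(vapply(spokes, function(s) max(s[[protein]]), numeric(1)))
  rows <- lapply(seq_along(spokes), function(i) {
    s <- spokes[[i]]
    radii <- s$radii_nm
    tb <- base(s$tubulin); pb <- base(s[[protein]])
    tp <- peak_in(radii, s$tubulin, min(radii), max(radii))
    out <- data.frame(triplet_index = i, angle_deg = s$angle_deg,
                      r_tubulin_nm = NA_real_, r_protein_nm = NA_real_,
                      delta_nm = NA_real_, resolved = FALSE)
    if (is.null(tp) || (tp$value - tb) < min_prominence * (tub_max - tb)) {
      return(out)
    }
    pp <- peak_in(radii, s[[protein]], tp$r - window_nm, tp$r + window_nm)
    if (is.null(pp) || (pp$value - pb) < min_prominence * (prot_max - pb)) {
      out$r_tubulin_nm <- tp$r
      return(out)
    }
    out$r_tubulin_nm <- tp$r
    out$r_protein_nm <- pp$r
    out$delta_nm <- tp$r - pp$r
    out$resolved <- TRUE
    out
  })
  offsets <- do.call(rbind, rows)
  res <- offsets$delta_nm[offsets$resolved]
  if (!length(res)) stop("no measurement: all spokes unresolved")
  structure(list(offsets = offsets,
                 mean_delta_nm = mean(res),
                 sd_delta_nm = stats::sd(res),
                 n_measurements = length(res)),
            class = "radial_map_result")
}

#' @export
print.radial_map_result <- function(x, ...) {
  cat(sprintf("Radial offsets: mean %.1f nm +/- %.1f (n = %d resolved)\n",
              x$mean_delta_nm,
              ifelse(is.na(x$sd_delta_nm), 0, x$sd_delta_nm),
              x$n_measurements))
  invisible(x)
}

#' Pool radial-offset results per experimental group
#'
#' Concatenates the resolved per-triplet offsets of several
#' `radial_map_result`s and summarizes them per group, per-measurement
#' pooled (each resolved spoke is one measurement).
#'
#' @param results List of `radial_map_result`s.
#' @param group_labels Character vector, one label per result.
#' @return Data frame with one row per group: `group`, `mean_delta_nm`,
#'   `sd_delta_nm`, `n`; attribute `"measurements"` holds the pooled
#'   per-measurement data frame.
#' @export
aggregate_offsets <- function(results, group_labels = rep("all", length(results))) {
  stopifnot(length(results) == length(group_labels), length(results) >= 1)
  meas <- do.call(rbind, lapply(seq_along(results), function(i) {
    o <- results[[i]]$offsets
    o <- o[o$resolved, , drop = FALSE]
    if (!nrow(o)) return(NULL)
    data.frame(group = group_labels[i], source = i, delta_nm = o$delta_nm)
  }))
  for (g in unique(group_labels)) {
    if (!g %in% meas$group) stop("missing group: no resolved offsets in '", g, "'")
  }
  agg <- do.call(rbind, lapply(split(meas, meas$group), function(d) {
    data.frame(group = d$group[1], mean_delta_nm = mean(d$delta_nm),
               sd_delta_nm = stats::sd(d$delta_nm), n = nrow(d))
  }))
  rownames(agg) <- NULL
  attr(agg, "measurements") <- meas
  agg
}
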