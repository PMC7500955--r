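# Internal numeric helpers shared by the measurement stages.
# Image convention throughout the package: a channel is a numeric matrix
# indexed [x, y] (first index = x / column direction of the acquisition),
# pixel centres at integer coordinates starting at 1.

# Bilinear interpolation of matrix `img` at real-valued coordinates.
# Points outside the grid return 0.
bilinear <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  out <- numeric(length(x))
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny
  if (!any(ok)) return(out)
  xf <- pmin(floor(x[ok]), nx - 1L); yf <- pmin(floor(y[ok]), ny - 1L)
  dx <- x[ok] - xf; dy <- y[ok] - yf
  i00 <- cbind(xf, yf); i10 <- cbind(xf + 1, yf)
  i01 <- cbind(xf, yf + 1); i11 <- cbind(xf + 1, yf + 1)
  out[ok] <- img[i00] * (1 - dx) * (1 - dy) + img[i10] * dx * (1 - dy) +
    img[i01] * (1 - dx) * dy + img[i11] * dx * dy
  out
}

# Three-point quadratic (parabolic) refinement of a discrete maximum.
# `values` is the profile, `i` the index of the discrete max; returns the
# fractional index of the interpolated vertex (clamped to +/- 0.5).
refine_peak <- function(values, i) {
  n <- length(values)
  if (i <= 1L || i >= n) return(as.numeric(i))
  y0 <- values[i - 1L]; y1 <- values[i]; y2 <- values[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom >= 0) return(as.numeric(i))  # not locally concave
  shift <- 0.5 * (y0 - y2) / denom
  i + max(-0.5, min(0.5, shift))
}

# Local maxima of a (possibly circular) trace with prominence and minimum
# separation constraints. Prominence of a peak = peak value minus the higher
# of the two deepest valleys separating it from a higher point (simple
# variant adequate for short traces). Returns sorted indices.
find_local_maxima <- function(x, min_prominence = 0, min_separation = 1L,
                              circular = FALSE) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  if (circular) {
    xl <- c(x[n], x[-n]); xr <- c(x[-1], x[1])
  } else {
    xl <- c(Inf, x[-n]); xr <- c(x[-1], Inf)
  }
  cand <- which(x > xl & x >= xr)
  if (!length(cand)) return(integer(0))
  # prominence: walk outwards until a strictly higher sample is met
  prom <- vapply(cand, function(i) {
    pv <- x[i]
    lowest <- function(step) {
      lo <- pv; j <- i
      for (k in seq_len(n)) {
        j <- j + step
        if (circular) j <- ((j - 1L) %% n) + 1L
        else if (j < 1L || j > n) break
        if (x[j] > pv) break
        lo <- min(lo, x[j])
        if (circular && j == i) break
      }
      lo
    }
    pv - max(lowest(1L), lowest(-1L))
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # non-maximum suppression by separation, strongest first
  keep <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep) {
    if (!length(sel)) { sel <- i; next }
    d <- abs(sel - i)
    if (circular) d <- pmin(d, n - d)
    if (all(d >= min_separation)) sel <- c(sel, i)
  }
  sort(sel)
}

# Circular moving average with odd window (used on angular traces).
circular_smooth <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  h <- window %/% 2L
  n <- length(x)
  xp <- c(x[(n - h + 1L):n], x, x[1L:h])
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(h + 1L):(h + n)]
}

# Outermost crossings of `level` by linear interpolation; returns positions
# (in `pos` units) of the first upward and last downward crossing around the
# global maximum. Used by the FWHM-style length rule.
outer_crossings <- function(pos, values, level) {
  above <- values > level
  if (!any(above)) return(NULL)
  first <- which(above)[1L]
  last <- which(above)[length(which(above))]
  left <- if (first == 1L) pos[1L] else {
    i <- first
    pos[i - 1L] + (level - values[i - 1L]) / (values[i] - values[i - 1L]) *
      (pos[i] - pos[i - 1L])
  }
  right <- if (last == length(values)) pos[length(pos)] else {
    i <- last
    pos[i] + (values[i] - level) / (values[i] - values[i + 1L]) *
      (pos[i + 1L] - pos[i])
  }
  c(left, right)
}

# Truncated-normal draw (truncated at `lower`), simple rejection sampler.
# Means used in this package sit several SDs above the truncation point, so
# rejection is essentially free and keeps the draw stream reproducible.
rtnorm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower)
  }
  out
}

# Derive a bounded per-item substream seed from a base seed.
substream_seed <- function(base_seed, index) {
  (as.integer(base_seed) + 1009L * as.integer(index)) %% 2147483647L
}
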