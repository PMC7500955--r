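# Group-comparison statistics: Mann-Whitney (exact by enumeration for small
# samples), one-way ANOVA with Holm-Sidak step-down comparisons, Fisher's
# exact test, unpaired t, and the star annotation convention.

#' Significance stars
#'
#' Maps a p-value to the usual convention: `*` p<0.05, `**` p<0.01,
#' `***` p<0.001, `****` p<0.0001, `ns` otherwise.
#' @param p P-value(s).
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***" else
      if (pi < 1e-2) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

group_summary <- function(...) {
  gs <- list(...)
  do.call(rbind, lapply(names(gs), function(nm) {
    data.frame(label = nm, mean = mean(gs[[nm]]), sd = stats::sd(gs[[nm]]),
               n = length(gs[[nm]]), stringsAsFactors = FALSE)
  }))
}

new_stats_summary <- function(test, statistic, p_value, groups,
                              pairwise = NULL) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 groups = groups, pairwise = pairwise,
                 stars = significance_stars(p_value)),
            class = "stats_summary")
}

#' @export
print.stats_summary <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p_value, x$stars))
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %s: %.3g +/- %.3g (n = %d)\n", g$label, g$mean, g$sd, g$n))
  }
  if (!is.null(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings
# (handles ties exactly); feasible for small totals.
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p by full enumeration of labelings when the pooled sample size is
#' at most `exact_max` (ties handled exactly); otherwise the normal
#' approximation with tie correction and continuity correction (via
#' [stats::wilcox.test()]).
#'
#' @param a,b Numeric samples.
#' @param labels Length-2 group labels for the summary.
#' @param exact_max Largest pooled n for exact enumeration (default 12).
#' @return A `stats_summary` (statistic = U of the first sample).
#' @export
mann_whitney <- function(a, b, labels = c("a", "b"), exact_max = 12) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  groups <- group_summary(a = a, b = b)
  groups$label <- labels
  if (isTRUE(all.equal(stats::var(c(a, b)), 0)) ||
      stats::var(c(a, b)) == 0) {
    return(new_stats_summary("Mann-Whitney", u, 1, groups))
  }
  p <- if (length(a) + length(b) <= exact_max) {
    mw_exact_p(a, b)
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                        correct = TRUE)$p.value)
  }
  new_stats_summary("Mann-Whitney", u, p, groups)
}

#' Holm-Sidak step-down adjustment
#'
#' Ordered raw p-values p(1) <= ... <= p(m); adjusted
#' p(i) = max over j <= i of 1 - (1 - p(j))^(m - j + 1), capped at 1.
#' Returned in the input order.
#'
#' @param p Raw p-values.
#' @return Adjusted p-values.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way ANOVA with Holm-Sidak pairwise comparisons
#'
#' Fits a one-way ANOVA and performs all pairwise comparisons using the
#' pooled residual variance (t statistics on the ANOVA error df), adjusting
#' by the Holm-Sidak step-down rule.
#'
#' @param groups Named list of numeric samples (>= 3 groups, each n >= 2).
#' @return A `stats_summary` with `statistic` = F, `p_value` = ANOVA p, and
#'   `pairwise` a data frame of comparisons (`p_raw`, `p_adj`, `stars`).
#' @export
anova_holm_sidak <- function(groups) {
  stopifnot(length(groups) >= 3, all(vapply(groups, length, 0L) >= 2))
  labs <- names(groups)
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(labs, vapply(groups, length, 0L)), levels = labs)
  N <- length(vals); k <- length(groups)
  gm <- vapply(groups, mean, 0); gn <- vapply(groups, length, 0L)
  ss_b <- sum(gn * (gm - mean(vals))^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- N - k
  if (ss_w == 0) {
    p_f <- if (ss_b > 0) 1e-16 else 1
    f <- if (ss_b > 0) Inf else 0
    mse <- .Machine$double.eps
  } else {
    mse <- ss_w / df2
    f <- (ss_b / df1) / mse
    p_f <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  cmb <- utils::combn(k, 2)
  pw <- data.frame(
    group1 = labs[cmb[1, ]], group2 = labs[cmb[2, ]],
    diff = gm[cmb[1, ]] - gm[cmb[2, ]], stringsAsFactors = FALSE)
  tt <- pw$diff / sqrt(mse * (1 / gn[cmb[1, ]] + 1 / gn[cmb[2, ]]))
  pw$p_raw <- 2 * stats::pt(-abs(tt), df2)
  pw$p_adj <- holm_sidak(pw$p_raw)
  pw$stars <- significance_stars(pw$p_adj)
  gsum <- do.call(group_summary, groups)
  new_stats_summary("One-way ANOVA + Holm-Sidak", f, p_f, gsum, pw)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A `stats_summary` (statistic = sample odds ratio estimate).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    groups <- data.frame(label = c("row1", "row2"),
                         mean = rowSums(table), sd = NA, n = rowSums(table))
    return(new_stats_summary("Fisher exact", NA_real_, 1, groups))
  }
  ft <- stats::fisher.test(table)
  groups <- data.frame(label = c("row1", "row2"),
                       mean = table[, 1] / rowSums(table), sd = NA,
                       n = rowSums(table))
  new_stats_summary("Fisher exact", unname(ft$estimate), ft$p.value, groups)
}

#' Two-sided unpaired t test
#'
#' Student's pooled-variance t by default; Welch's variant by
#' `welch = TRUE`.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param welch Use the Welch (unequal-variance) variant.
#' @param labels Group labels.
#' @return A `stats_summary` (statistic = t).
#' @export
unpaired_t <- function(a, b, welch = FALSE, labels = c("a", "b")) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  groups <- group_summary(a = a, b = b)
  groups$label <- labels
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_stats_summary("Unpaired t", 0, 1, groups))
    }
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  new_stats_summary(if (welch) "Welch t" else "Unpaired t",
                    unname(tt$statistic), tt$p.value, groups)
}
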