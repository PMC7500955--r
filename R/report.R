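# Run-level report: per-condition summaries of every measured metric with
# the configured group tests and star annotations.

#' Build a per-condition measurement report
#'
#' Summarizes every numeric metric column per group (mean, SD, n) and
#' applies a group test per metric: for two groups the configured two-group
#' test, for three or more a one-way ANOVA with Holm-Sidak comparisons.
#'
#' @param measurements Data frame: one row per measured image/cell, one
#'   column naming the group plus numeric metric columns.
#' @param group_col Name of the grouping column (default `"group"`).
#' @param two_group_test `"mann-whitney"` (default) or `"t"`; ignored with
#'   more than two groups.
#' @param metrics Metric columns to summarize (default: every numeric
#'   column).
#' @return A list of class `run_report`: `summary` (data frame: metric,
#'   group, mean, sd, n), `tests` (named list of `stats_summary`, absent
#'   with a single group), `log` (character vector recording settings).
#' @export
build_report <- function(measurements, group_col = "group",
                         two_group_test = c("mann-whitney", "t"),
                         metrics = NULL) {
  two_group_test <- match.arg(two_group_test)
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1)
  if (!group_col %in% names(measurements)) {
    stop("missing group: column '", group_col, "' not found")
  }
  g <- as.character(measurements[[group_col]])
  if (is.null(metrics)) {
    metrics <- names(measurements)[vapply(measurements, is.numeric, TRUE)]
    metrics <- setdiff(metrics, group_col)
  }
  labs <- unique(g)
  summ <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(labs, function(lb) {
      v <- measurements[[m]][g == lb]
      v <- v[is.finite(v)]
      data.frame(metric = m, group = lb, mean = mean(v),
                 sd = stats::sd(v), n = length(v), stringsAsFactors = FALSE)
    }))
  }))
  tests <- NULL
  if (length(labs) >= 2) {
    tests <- lapply(metrics, function(m) {
      samples <- lapply(labs, function(lb) {
        v <- measurements[[m]][g == lb]
        v[is.finite(v)]
      })
      names(samples) <- labs
      if (length(labs) == 2) {
        if (two_group_test == "mann-whitney") {
          mann_whitney(samples[[1]], samples[[2]], labels = labs)
        } else {
          unpaired_t(samples[[1]], samples[[2]], labels = labs)
        }
      } else {
        anova_holm_sidak(samples)
      }
    })
    names(tests) <- metrics
  }
  log <- c(sprintf("groups: %s", paste(labs, collapse = ", ")),
           sprintf("metrics: %s", paste(metrics, collapse = ", ")),
           sprintf("two-group test: %s", two_group_test))
  structure(list(summary = summ, tests = tests, log = log),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Measurement report\n")
  for (m in unique(x$summary$metric)) {
    s <- x$summary[x$summary$metric == m, ]
    star <- if (!is.null(x$tests)) x$tests[[m]]$stars else ""
    cat(sprintf("  %s%s\n", m,
                if (nzchar(star) && !is.na(star)) paste0("  [", star, "]") else ""))
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-12s %8.3g +/- %-8.3g n = %d\n",
                  s$group[i], s$mean[i], s$sd[i], s$n[i]))
    }
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `summary.csv`, `stats.json` and `run.log` into `dir`.
#'
#' @param report A `run_report` from [build_report()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  tests <- lapply(report$tests, function(t) {
    list(test = t$test, statistic = t$statistic, p_value = t$p_value,
         stars = t$stars,
         pairwise = if (!is.null(t$pairwise)) t$pairwise else NULL)
  })
  jsonlite::write_json(tests, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}
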