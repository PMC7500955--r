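test_that("Mann-Whitney matches exhaustive enumeration on small samples", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney(1:3, 4:6)$p_value, 0.1)
  set.seed(11)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:5, na, replace = TRUE)  # ties likely
    b <- sample(1:5, nb, replace = TRUE)
    expect_equal(mann_whitney(a, b)$p_value, oracle_mw_p(a, b),
                 info = sprintf("a=%s b=%s", toString(a), toString(b)))
  }
  # large-sample approximation close to exact at 6 + 6 (the continuity
  # corrected normal approximation is accurate to about 0.01 on average at
  # this size, with occasional deviations up to about 0.02)
  set.seed(12)
  diffs <- vapply(1:20, function(i) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    abs(mann_whitney(a, b)$p_value -
          mann_whitney(a, b, exact_max = 0)$p_value)
  }, numeric(1))
  expect_lt(mean(diffs), 0.01)
  expect_lt(max(diffs), 0.02)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value,
               0.00793650793650794, tolerance = 1e-10)
  expect_equal(fisher_exact(matrix(c(3, 3, 3, 3), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2))$p_value, 1)
  set.seed(13)
  for (i in 1:30) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-9, info = toString(tab))
  }
})

test_that("Holm-Sidak adjustment is monotone, order free and conservative", {
  expect_equal(holm_sidak(0.02), 0.02)
  set.seed(14)
  for (i in 1:15) {
    p <- runif(sample(2:8, 1))
    adj <- holm_sidak(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))   # step-down monotone
    perm <- sample(length(p))
    expect_equal(holm_sidak(p[perm]), adj[perm])
  }
  # manual check of the step-down formula at m = 3
  p <- c(0.01, 0.04, 0.03)
  m <- 3
  expect_equal(holm_sidak(p),
               c(1 - (1 - 0.01)^3,
                 max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2, 1 - (1 - 0.04)^1),
                 max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2)))
})

test_that("one-way ANOVA agrees with the base fit and handles degeneracy", {
  set.seed(15)
  g <- list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 1))
  res <- anova_holm_sidak(g)
  ref <- stats::oneway.test(y ~ f,
                            data = data.frame(y = unlist(g),
                                              f = rep(names(g), each = 8)),
                            var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw - 1e-12))
  # zero within-group variance with distinct means
  gz <- list(a = c(1, 1), b = c(2, 2), c = c(3, 3))
  expect_lt(anova_holm_sidak(gz)$p_value, 1e-15)
})

test_that("unpaired t reproduces the pooled-variance formula", {
  r <- unpaired_t(1:4, 2:5)
  expect_equal(r$statistic, -1.095445, tolerance = 1e-6)
  expect_equal(r$p_value, 0.3153, tolerance = 1e-3)
  expect_equal(unpaired_t(c(2, 2), c(2, 2))$p_value, 1)
  # Welch equals pooled when the variances are equal
  a <- c(1, 2, 3, 4); b <- c(5, 6, 7, 8)
  expect_equal(unpaired_t(a, b, welch = TRUE)$statistic,
               unpaired_t(a, b)$statistic)
})

test_that("stars follow the reporting convention", {
  expect_equal(significance_stars(c(0.2, 0.03, 0.003, 3e-4, 3e-5)),
               c("ns", "*", "**", "***", "****"))
})

test_that("the run report recomputes group summaries faithfully", {
  set.seed(16)
  df <- data.frame(group = rep(c("ctl", "trt"), each = 12),
                   length_nm = c(rnorm(12, 434, 30), rnorm(12, 500, 30)),
                   coverage = c(rnorm(12, 57, 5), rnorm(12, 24, 5)))
  rep_ <- build_report(df)
  for (m in c("length_nm", "coverage")) {
    for (g in c("ctl", "trt")) {
      expect_equal(rep_$summary$mean[rep_$summary$metric == m &
                                       rep_$summary$group == g],
                   mean(df[[m]][df$group == g]))
    }
  }
  expect_named(rep_$tests, c("length_nm", "coverage"))
  expect_equal(rep_$tests$length_nm$test, "Mann-Whitney")
  # stars appear on the p scale of the test
  expect_equal(significance_stars(0.003), "**")
  # single group: summaries only
  rep1 <- build_report(df[df$group == "ctl", ])
  expect_null(rep1$tests)
  # report bundle writes all artefacts
  dir <- file.path(tempdir(), "reportdir")
  write_report(rep_, dir)
  expect_true(all(file.exists(file.path(dir, c("summary.csv", "stats.json",
                                               "run.log")))))
  expect_error(build_report(df, group_col = "nope"), "missing group")
})
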