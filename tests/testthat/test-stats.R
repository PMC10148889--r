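test_that("Welch's t matches the closed-form oracle and its invariances", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  got <- welch_t(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  scaled <- welch_t(10 * a, 10 * b)
  expect_equal(scaled$t, got$t, tolerance = 1e-12)

  set.seed(5)
  x <- rnorm(12); y <- rnorm(17, 0.4, 2)
  g2 <- welch_t(x, y); w2 <- oracle_welch(x, y)
  expect_equal(g2$t, w2$t, tolerance = 1e-10)
  expect_equal(g2$df, w2$df, tolerance = 1e-10)

  expect_error(welch_t(1, c(1, 2)), "n >= 2")
  expect_error(welch_t(c(1, 1, 1), c(2, 2, 2)), "zero variance")
})

test_that("Grubbs critical values match the published table and the filter removes gross outliers", {
  # two-sided critical values at alpha = 0.05 (standard reference table)
  expect_equal(cagematch:::grubbs_critical(10, 0.05), 2.290, tolerance = 1e-3)
  expect_equal(cagematch:::grubbs_critical(20, 0.05), 2.709, tolerance = 1e-3)
  expect_equal(cagematch:::grubbs_critical(5, 0.05), 1.715, tolerance = 1e-3)

  res <- grubbs_filter(c(1, 1.1, 0.9, 50))
  expect_equal(res$removed, 50)
  expect_equal(sort(res$retained), c(0.9, 1, 1.1))

  sym <- grubbs_filter(c(-2, -1, 0, 1, 2))
  expect_length(sym$removed, 0)

  expect_warning(small <- grubbs_filter(c(1, 2)), "n >= 3")
  expect_equal(small$retained, c(1, 2))
})

test_that("Grubbs filtering is idempotent and has alpha-level behavior on clean samples", {
  set.seed(20)
  removed_any <- 0
  for (i in 1:2000) {
    x <- rnorm(20)
    res <- grubbs_filter(x)
    if (length(res$removed)) {
      removed_any <- removed_any + 1
      again <- grubbs_filter(res$retained)
      expect_length(again$removed, 0)
    }
  }
  expect_lt(removed_any / 2000, 0.10)
})

test_that("Fisher's exact p equals brute-force hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)

  tab <- matrix(c(8, 1, 2, 9), 2)
  expect_equal(fisher_exact_2x2(tab)$p, oracle_fisher_p(tab),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(t(tab))$p, fisher_exact_2x2(tab)$p,
               tolerance = 1e-12)

  set.seed(30)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Bonferroni scales by the family size and caps at 1", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(c(0.2, 0.9), 1), c(0.2, 0.9))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("the mixed model recovers a null contrast on constant data", {
  df <- data.frame(amplitude = rep(0.02, 40),
                   mouse = rep(paste0("m", 1:8), each = 5),
                   group = rep(c("a", "b"), each = 20))
  fit <- suppressWarnings(suppressMessages(fit_group_lmm(df)))
  expect_equal(tidy(fit)$estimate, 0, tolerance = 1e-12)
})

test_that("with no between-mouse variance the LMM contrast matches the pooled difference", {
  set.seed(40)
  df <- data.frame(
    amplitude = c(rnorm(80, 0.02, 0.01), rnorm(80, 0.05, 0.01)),
    mouse = rep(paste0("m", 1:16), each = 10),
    group = rep(c("ctl", "high"), each = 80)
  )
  fit <- suppressMessages(fit_group_lmm(df, ref = "ctl"))
  pooled <- mean(df$amplitude[df$group == "high"]) -
    mean(df$amplitude[df$group == "ctl"])
  expect_equal(tidy(fit)$estimate, pooled, tolerance = abs(pooled) * 0.01)
  expect_equal(glance(fit)$n_mice, 16L)
})

test_that("the LMM validates its design and exposes both df conventions", {
  df <- data.frame(amplitude = rnorm(20), mouse = rep(c("m1", "m2"), 10),
                   group = "a")
  expect_error(fit_group_lmm(df), "2 groups")
  df2 <- data.frame(amplitude = rnorm(20), mouse = "m1",
                    group = rep(c("a", "b"), 10))
  expect_error(fit_group_lmm(df2), "2 mice")

  set.seed(41)
  df3 <- data.frame(
    amplitude = rnorm(60, rep(c(0, 0.04), each = 30), 0.01),
    mouse = rep(paste0("m", 1:12), each = 5),
    group = rep(c("a", "b"), each = 30)
  )
  bw <- suppressMessages(fit_group_lmm(df3, ddf = "between_within"))
  rs <- suppressMessages(fit_group_lmm(df3, ddf = "residual"))
  expect_equal(tidy(bw)$df, 12 - 2)
  expect_equal(tidy(rs)$df, 60 - 2)
  expect_equal(tidy(bw)$estimate, tidy(rs)$estimate)
})

test_that("the repeated-measures ANOVA contract runs on a condition-by-treatment design", {
  set.seed(42)
  df <- expand.grid(subject = paste0("s", 1:12), within = c("pre", "post"))
  df$between <- rep(c("ctl", "drug"), each = 6)
  df$value <- rnorm(nrow(df)) +
    ifelse(df$within == "post" & df$between == "drug", 1.5, 0)
  res <- rm_two_way_anova(df)
  rows <- unlist(lapply(res, function(st) rownames(st[[1]])))
  expect_true(any(grepl("between:within", rows)))
})
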