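#' Welch's unpaired two-sample t test
#'
#' Two-sided t test insensitive to unequal variances, with
#' Welch--Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return A one-row tibble: `estimate` (mean(a) - mean(b)), `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) abort("each sample needs n >= 2")
  if (var(a) == 0 && var(b) == 0) abort("zero variance in both samples")
  tt <- t.test(a, b, var.equal = FALSE)
  tibble::tibble(estimate = mean(a) - mean(b),
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value)
}

# Two-sided Grubbs critical value for sample size n at level alpha.
grubbs_critical <- function(n, alpha = 0.05) {
  tc <- qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
}

#' Iterative Grubbs outlier removal
#'
#' Repeatedly tests the most extreme point (`G = max|x - mean| / sd`)
#' against the two-sided Grubbs critical value at `alpha`; while it exceeds
#' the critical value the point is removed and the test repeated, stopping
#' when no point exceeds it or only three points remain.
#'
#' @param x Numeric sample.
#' @param alpha Significance level (default 0.05).
#' @return A list: `retained`, `removed`.
#' @export
grubbs_filter <- function(x, alpha = 0.05) {
  if (length(x) < 3L) {
    warn("Grubbs test needs n >= 3; sample returned unchanged")
    return(list(retained = x, removed = numeric(0)))
  }
  removed <- numeric(0)
  repeat {
    n <- length(x)
    if (n < 3L) break
    s <- sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g > grubbs_critical(n, alpha) && n > 3L) {
      i <- which.max(dev)
      removed <- c(removed, x[i])
      x <- x[-i]
    } else if (g > grubbs_critical(n, alpha) && n == 3L) {
      # n = 3 is the floor: flag but keep
      break
    } else {
      break
    }
  }
  list(retained = x, removed = removed)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p value: the sum of hypergeometric probabilities, over tables
#' with the observed margins, that do not exceed the observed table's
#' probability.  Delegates to [stats::fisher.test()].
#'
#' @param tab A 2x2 matrix of non-negative integer counts.
#' @return A list: `odds_ratio` (conditional MLE), `p`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) abort("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("cells must be non-negative integers")
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, m * p)`, with `m` supplied so that post-hoc contrasts can
#' be corrected for a family larger than the vector at hand.
#'
#' @param p Numeric p values in `[0, 1]`.
#' @param m Number of comparisons in the family (default `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Trial-level mixed-effects group comparison
#'
#' Fits `amplitude ~ group + (1 | mouse)` by REML ([lme4::lmer()]): repeated
#' event-locked measurements per animal are modelled with a random intercept
#' per mouse, so group contrasts are tested at the right level rather than
#' pooling events.  Contrasts are each non-reference group versus the
#' reference level.
#'
#' Degrees of freedom: `"between_within"` (default) uses
#' `n_mice - n_groups`, the between-cluster df appropriate for a factor that
#' varies between animals; `"residual"` uses `n_events - n_groups`, the
#' convention under which df are often printed alongside such models.
#'
#' @param data A data frame with one row per event.
#' @param amplitude,mouse,group Column names (strings).
#' @param ref Reference group level (default: first level).
#' @param ddf Degrees-of-freedom method.
#' @return An object of class `cm_lmm`; see [tidy.cm_lmm()] and
#'   [glance.cm_lmm()].
#' @export
fit_group_lmm <- function(data, amplitude = "amplitude", mouse = "mouse",
                          group = "group", ref = NULL,
                          ddf = c("between_within", "residual")) {
  ddf <- match.arg(ddf)
  df <- tibble::tibble(
    amplitude = data[[amplitude]],
    mouse = as.character(data[[mouse]]),
    group = as.character(data[[group]])
  )
  groups <- unique(df$group)
  if (length(groups) < 2L) abort("need at least 2 groups")
  mice_per_group <- tapply(df$mouse, df$group, function(m) length(unique(m)))
  if (any(mice_per_group < 2L)) abort("need at least 2 mice per group")
  if (length(unique(df$mouse)) < 2L) abort("singular design: one mouse total")
  if (!is.null(ref)) {
    df$group <- stats::relevel(factor(df$group), ref = ref)
  } else {
    df$group <- factor(df$group)
  }
  fit <- lme4::lmer(amplitude ~ group + (1 | mouse), data = df, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n_groups <- nlevels(df$group)
  n_mice <- length(unique(df$mouse))
  dof <- switch(ddf,
                between_within = n_mice - n_groups,
                residual = nrow(df) - n_groups)
  idx <- seq_along(fe)[-1L] # drop intercept
  contrasts <- tibble::tibble(
    term = sub("^group", "", names(fe)[idx]),
    reference = levels(df$group)[1L],
    estimate = unname(fe[idx]),
    std_error = unname(se[idx]),
    t = unname(fe[idx] / se[idx]),
    df = dof,
    p = 2 * pt(-abs(unname(fe[idx] / se[idx])), df = dof)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(fit = fit, contrasts = contrasts, ddf = ddf,
         n_events = nrow(df), n_mice = n_mice, n_groups = n_groups,
         random_intercept_var = vc$vcov[vc$grp == "mouse"],
         residual_var = vc$vcov[vc$grp == "Residual"]),
    class = "cm_lmm"
  )
}

#' @export
print.cm_lmm <- function(x, ...) {
  cat(sprintf("<cm_lmm> amplitude ~ group + (1 | mouse): %d events, %d mice, %d groups (ddf: %s)\n",
              x$n_events, x$n_mice, x$n_groups, x$ddf))
  print(x$contrasts)
  invisible(x)
}

#' Tidy the group contrasts of a mixed-model fit
#'
#' @param x A `cm_lmm` from [fit_group_lmm()].
#' @param ... Unused.
#' @return A tibble with one row per non-reference group: `term`,
#'   `reference`, `estimate`, `std_error`, `t`, `df`, `p`.
#' @exportS3Method generics::tidy
tidy.cm_lmm <- function(x, ...) {
  x$contrasts
}

#' One-row model summary of a mixed-model fit
#'
#' @param x A `cm_lmm` from [fit_group_lmm()].
#' @param ... Unused.
#' @return A one-row tibble: sizes and variance components.
#' @exportS3Method generics::glance
glance.cm_lmm <- function(x, ...) {
  tibble::tibble(
    n_events = x$n_events, n_mice = x$n_mice, n_groups = x$n_groups,
    random_intercept_var = x$random_intercept_var,
    residual_var = x$residual_var,
    ddf = x$ddf
  )
}

#' Repeated-measures two-way ANOVA (delegated)
#'
#' Thin contract over [stats::aov()] with an error stratum per subject, for
#' condition-by-treatment designs with repeated measures; provided for
#' end-to-end workflows, not re-derived.
#'
#' @param data One row per observation.
#' @param value,subject,within,between Column names (strings): the measured
#'   value, the repeated-measures unit, the within-subject factor and the
#'   between-subject factor.
#' @return The `summary.aov` object of the fitted model.
#' @export
rm_two_way_anova <- function(data, value = "value", subject = "subject",
                             within = "within", between = "between") {
  df <- data.frame(
    value = data[[value]],
    subject = factor(data[[subject]]),
    within = factor(data[[within]]),
    between = factor(data[[between]])
  )
  fit <- stats::aov(value ~ between * within + Error(subject / within),
                    data = df)
  summary(fit)
}
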