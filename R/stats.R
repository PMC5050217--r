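# Hypothesis tests and interval estimators used in the baseline table and
# the stratified comparisons. Standard tests are delegated to the stats
# package (t.test, wilcox.test, fisher.test, aov) and to multcomp for the
# Dunnett many-to-one adjustment; the continuity-corrected Wilson interval
# is computed from the closed form. All p-values are two-tailed.

.new_test_result <- function(method, statistic, p, df = NA_real_,
                             exact = NA, extra = NULL) {
  structure(c(list(method = method, statistic = unname(statistic),
                   p_two_tailed = unname(p), df = unname(df), exact = exact),
              extra),
            class = "burncohort_test")
}

#' @export
print.burncohort_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      if (!is.na(x$df)) paste0(", df = ", format(x$df)),
      ", two-tailed p = ", format.pval(x$p_two_tailed), "\n", sep = "")
  invisible(x)
}

#' Two-sample equal-variance t-test
#'
#' Pooled-variance (Student) t-test with `n1 + n2 - 2` degrees of freedom
#' and a two-tailed p-value.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return A test result with `statistic`, `df`, `p_two_tailed`.
#' @export
t_test_equal_var <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(.new_test_result("Two-sample equal-variance t-test", 0, 1,
                              df = length(x) + length(y) - 2))
    }
    stop("zero pooled variance: samples are constant")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  .new_test_result("Two-sample equal-variance t-test", ht$statistic,
                   ht$p.value, df = ht$parameter)
}

#' Equal-variance t-test from printed summary statistics
#'
#' The same pooled-variance t-test driven by group means, SDs and sizes, so
#' printed baseline-table summaries can be re-tested without raw data. When
#' the summaries are computed from raw samples the result is identical to
#' [t_test_equal_var()].
#'
#' @param m1,s1,n1 Mean, SD and size of the first group.
#' @param m2,s2,n2 Mean, SD and size of the second group.
#' @return A test result with `statistic`, `df`, `p_two_tailed`.
#' @export
t_test_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) {
      return(.new_test_result("Two-sample equal-variance t-test (summary)",
                              0, 1, df = n1 + n2 - 2))
    }
    stop("zero pooled variance with unequal means")
  }
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  .new_test_result("Two-sample equal-variance t-test (summary)", tstat,
                   2 * stats::pt(-abs(tstat), df), df = df)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-tailed Mann-Whitney U test. With at most 8 observations per group
#' and no ties the exact permutation distribution is used; otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) computation;
#'   default `NULL` applies the crossover rule above (ties always force the
#'   approximation).
#' @return A test result with the U `statistic` and `p_two_tailed`; `exact`
#'   records which computation was used.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- length(x) <= 8 && length(y) <= 8 && !ties
  if (exact && ties) {
    stop("exact Mann-Whitney p-value is unavailable with ties")
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  .new_test_result("Mann-Whitney U test", ht$statistic, ht$p.value,
                   exact = exact)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-tailed p-value by summing hypergeometric probabilities no larger
#' than that of the observed table. A table with a zero margin is
#' degenerate and returns p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A test result with the odds-ratio estimate as `statistic` and
#'   `p_two_tailed`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(.new_test_result("Fisher's exact test", NA_real_, 1, exact = TRUE))
  }
  ht <- stats::fisher.test(table)
  .new_test_result("Fisher's exact test", ht$estimate, ht$p.value,
                   exact = TRUE)
}

#' One-way ANOVA with Dunnett's many-to-one post hoc test
#'
#' Overall F test across groups, then each non-reference group compared to
#' the reference with two-sided p-values adjusted by the single-step
#' Dunnett procedure (maximum of an equicorrelated multivariate t,
#' integrated numerically). A fixed RNG seed is applied around the
#' quasi-Monte-Carlo integration so adjusted p-values are reproducible to
#' well below 1e-3.
#'
#' @param groups List of numeric samples (>= 2 groups of >= 2 observations;
#'   groups of fewer than 2 observations are dropped with a warning).
#' @param reference_index Index of the reference (control) group, default 1.
#' @return A test result with the overall `statistic` (F), `df` (a length-2
#'   vector), `p_two_tailed` (overall ANOVA p) and `dunnett`: a data frame
#'   of per-comparison estimates and adjusted p-values.
#' @export
anova_dunnett <- function(groups, reference_index = 1) {
  if (reference_index < 1 || reference_index > length(groups)) {
    stop("reference_index out of range")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ref_name <- names(groups)[reference_index]
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    warning("dropping group(s) with fewer than 2 observations: ",
            paste(names(groups)[sizes < 2], collapse = ", "))
    if (sizes[reference_index] < 2) {
      stop("reference group has fewer than 2 observations")
    }
    groups <- groups[sizes >= 2]
  }
  if (length(groups) < 2) stop("need at least 2 usable groups")
  dat <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  dat$g <- stats::relevel(dat$g, ref = ref_name)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  p_overall <- an[["Pr(>F)"]][1]
  cmp <- withr_seed(20160216, {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    summary(gl, test = multcomp::adjusted("single-step"))
  })
  dunnett <- data.frame(
    comparison = names(cmp$test$coefficients),
    estimate = unname(cmp$test$coefficients),
    p_adjusted = as.numeric(cmp$test$pvalues),
    stringsAsFactors = FALSE
  )
  .new_test_result("One-way ANOVA with Dunnett post hoc", fstat, p_overall,
                   df = an$Df[1:2],
                   extra = list(dunnett = dunnett, reference = ref_name))
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Wilson score interval with continuity correction
#'
#' Confidence interval for a binomial proportion by the Wilson score method
#' with Newcombe's continuity correction, clamped to \[0, 1\]; the lower
#' bound is exactly 0 when there are no successes and the upper bound
#' exactly 1 when all trials succeed.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return A list of class `"binomial_ci"` with `successes`, `n`,
#'   `estimate`, `level`, `lo`, `hi`.
#' @export
wilson_ci_cc <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  p <- successes / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- if (successes == 0) 0 else {
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
      (2 * (n + z^2))
  }
  hi <- if (successes == n) 1 else {
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
      (2 * (n + z^2))
  }
  structure(list(successes = successes, n = n, estimate = p, level = level,
                 lo = max(0, lo), hi = min(1, hi)),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f, %g%% Wilson CC CI (%.3f, %.3f)\n",
              x$successes, x$n, x$estimate, 100 * x$level, x$lo, x$hi))
  invisible(x)
}

#' Uncorrected Wilson score interval
#'
#' The plain (no continuity correction) Wilson interval; provided for
#' comparison with [wilson_ci_cc()], which is always at least as wide for
#' interior counts.
#'
#' @inheritParams wilson_ci_cc
#' @return A list of class `"binomial_ci"`.
#' @export
wilson_ci <- function(successes, n, level = 0.95) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  p <- successes / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  structure(list(successes = successes, n = n, estimate = p, level = level,
                 lo = max(0, center - half), hi = min(1, center + half)),
            class = "binomial_ci")
}

#' Significance annotation thresholds
#'
#' The annotation convention used in the stratified-comparison figures:
#' `"**"` for p < 0.05, `"*"` for p < 0.1, empty otherwise. This is a
#' labelling rule only, not a different test.
#'
#' @param p Numeric p-value(s).
#' @return Character vector of annotations.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", ""))
}
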