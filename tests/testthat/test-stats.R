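test_that("equal-variance t-test matches the textbook formula", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  r <- t_test_equal_var(x, y)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_tailed, 1)

  r2 <- t_test_equal_var(c(1, 2, 3), c(101, 102, 103))
  expect_lt(r2$p_two_tailed, 1e-6)

  set.seed(21)
  for (trial in 1:20) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), mean = 0.4)
    got <- t_test_equal_var(a, b)
    want <- oracle_pooled_t(a, b)
    expect_equal(got$statistic, want$t, tolerance = 1e-12)
    expect_equal(got$p_two_tailed, want$p, tolerance = 1e-12)
  }
  expect_error(t_test_equal_var(c(1, 1), c(2, 2)), "pooled variance")
})

test_that("summary t-test reproduces printed case/non-case p-values", {
  # cytokine ratio groups: 0.200+/-0.154 (n=17) vs 0.067+/-0.072 (n=17)
  r <- t_test_from_summary(0.200, 0.154, 17, 0.067, 0.072, 17)
  expect_equal(r$p_two_tailed, 0.0029, tolerance = 0.0005 / 0.0029)
  # TBSA groups: 31.9+/-11.2 vs 51.2+/-20.0
  r2 <- t_test_from_summary(31.9, 11.2, 17, 51.2, 20.0, 17)
  expect_equal(r2$p_two_tailed, 0.0015, tolerance = 0.0005 / 0.0015)

  expect_equal(t_test_from_summary(5, 1, 10, 5, 2, 10)$statistic, 0)

  # summary-driven equals raw-driven when summaries come from the raw data
  set.seed(22)
  a <- rnorm(12); b <- rnorm(15, 1)
  raw <- t_test_equal_var(a, b)
  summ <- t_test_from_summary(mean(a), sd(a), 12, mean(b), sd(b), 15)
  expect_equal(summ$statistic, raw$statistic, tolerance = 1e-12)
  expect_equal(summ$p_two_tailed, raw$p_two_tailed, tolerance = 1e-12)
})

test_that("Mann-Whitney switches between exact and tie-corrected modes", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_two_tailed, 1 / 3, tolerance = 1e-12)
  expect_true(r$exact)

  # identical tied samples: U at its null center, approximation, p ~ 1
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r2$statistic), 4.5)  # n1*n2/2
  expect_false(r2$exact)
  expect_equal(r2$p_two_tailed, 1)

  r3 <- mann_whitney(rnorm(20), rnorm(20, 5))
  expect_false(r3$exact)
  expect_lt(r3$p_two_tailed, 0.001)
  expect_error(mann_whitney(c(1, 1), c(1, 2), exact = TRUE), "ties")
})

test_that("Fisher's exact test: printed burn-wound split, symmetry, degeneracy", {
  tab <- rbind(c(3, 14), c(15, 2))
  r <- fisher_exact_2x2(tab)
  expect_lt(r$p_two_tailed, 0.0001)
  expect_equal(fisher_exact_2x2(t(tab))$p_two_tailed, r$p_two_tailed)
  expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_two_tailed, r$p_two_tailed)

  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))$p_two_tailed, 1)
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(5, 5)))$p_two_tailed, 1)
})

test_that("ANOVA with Dunnett adjustment behaves across group structures", {
  # three identical groups: F ~ 0, all adjusted p ~ 1
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  r <- anova_dunnett(g)
  expect_lt(r$statistic, 1e-10)
  expect_true(all(r$dunnett$p_adjusted > 0.999))

  # two groups: Dunnett equals the unadjusted pooled comparison
  set.seed(23)
  a <- rnorm(10); b <- rnorm(10, 1)
  r2 <- anova_dunnett(list(ctrl = a, trt = b))
  expect_equal(r2$dunnett$p_adjusted,
               t_test_equal_var(a, b)$p_two_tailed, tolerance = 1e-3)

  # four groups, one far shifted: only that group flags
  g4 <- list(ref = rnorm(8), g1 = rnorm(8), g2 = rnorm(8),
             g3 = rnorm(8) + 5)
  r4 <- anova_dunnett(g4)
  p <- r4$dunnett$p_adjusted[match(c("g1", "g2", "g3"),
                                   sub(" - .*", "", r4$dunnett$comparison))]
  expect_gt(p[1], 0.5)
  expect_gt(p[2], 0.5)
  expect_lt(p[3], 0.001)

  # adjusted p never smaller than the unadjusted pairwise p, up to the
  # tolerance of the multivariate-t integration
  for (gname in c("g1", "g2", "g3")) {
    padj <- r4$dunnett$p_adjusted[sub(" - .*", "", r4$dunnett$comparison)
                                  == gname]
    expect_gte(padj + 1e-4,
               t_test_equal_var(g4$ref, g4[[gname]])$p_two_tailed)
  }

  expect_error(anova_dunnett(g, reference_index = 9), "out of range")
})

test_that("Wilson CC intervals reproduce printed bounds and invariants", {
  expect_equal(round(wilson_ci_cc(14, 17)$lo, 2), 0.56)
  expect_equal(round(wilson_ci_cc(14, 17)$hi, 2), 0.95)
  expect_equal(round(wilson_ci_cc(11, 17)$lo, 2), 0.39)
  expect_equal(wilson_ci_cc(0, 10)$lo, 0)
  expect_equal(wilson_ci_cc(10, 10)$hi, 1)

  for (k in 0:17) {
    cc <- wilson_ci_cc(k, 17)
    plain <- wilson_ci(k, 17)
    expect_lte(cc$lo, cc$estimate)
    expect_gte(cc$hi, cc$estimate)
    if (k > 0 && k < 17) {
      expect_lt(cc$lo, plain$lo)   # CC interval strictly wider inside
      expect_gt(cc$hi, plain$hi)
    }
  }
})

test_that("significance stars follow the figure annotation thresholds", {
  expect_equal(significance_stars(c(0.04, 0.07, 0.2)), c("**", "*", ""))
})
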