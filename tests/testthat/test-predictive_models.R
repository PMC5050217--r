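test_that("intercept-only Firth fit equals the augmented-cell closed form", {
  for (k in c(0, 3, 10)) {
    y <- rep(c(1, 0), c(k, 10 - k))
    f <- firth_logistic_fit(matrix(1, 10, 1), y)
    expect_true(f$converged)
    expect_equal(unname(f$coefficients), qlogis((k + 0.5) / 11),
                 tolerance = 1e-5)
  }
})

test_that("Firth estimates stay finite under complete separation and match the optimizer oracle", {
  X <- cbind(1, c(0, 0, 1, 1))
  y <- c(0, 0, 1, 1)
  f <- firth_logistic_fit(X, y)
  expect_true(f$converged)
  expect_true(all(is.finite(f$coefficients)))
  expect_lt(f$max_score, 1e-6)
  want <- oracle_firth(X, y, starts = list(c(0, 0), c(-1, 2)))
  expect_equal(unname(f$coefficients), want, tolerance = 1e-4)

  # small non-separated datasets against the same oracle
  set.seed(31)
  for (trial in 1:10) {
    Xt <- cbind(1, round(rnorm(4), 1))
    yt <- rbinom(4, 1, 0.5)
    ft <- firth_logistic_fit(Xt, yt)
    wt <- oracle_firth(Xt, yt, starts = list(c(0, 0), ft$coefficients * 0.9))
    expect_equal(unname(ft$coefficients), wt, tolerance = 1e-4)
  }
})

test_that("Firth penalty vanishes asymptotically: parameter recovery at n = 2000", {
  set.seed(32)
  beta <- c(-0.5, 1.2)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(beta[1] + beta[2] * x))
  f <- firth_logistic_fit(cbind(1, x), y)
  expect_true(f$converged)
  expect_lt(abs(f$coefficients[1] - beta[1]), 3 * f$se[1])
  expect_lt(abs(f$coefficients[2] - beta[2]), 3 * f$se[2])
})

test_that("Firth optimum properties: score residual and likelihood gain", {
  set.seed(33)
  X <- cbind(1, rnorm(20), rnorm(20))
  y <- rbinom(20, 1, 0.4)
  f <- firth_logistic_fit(X, y)
  expect_lt(f$max_score, 1e-6)
  expect_gte(f$loglik_penalized,
             burncohort:::penalized_loglik(X, y, rep(0, 3)))
  expect_error(firth_logistic_fit(cbind(1, x1 = 1:5, x2 = 2 * (1:5)),
                                  rep(0:1, length.out = 5)),
               "rank deficient")
})

test_that("AUROC equals brute-force pairwise counting", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(2, 6), rep(0:1, 3)), 0.5)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")

  set.seed(34)
  for (trial in 1:50) {
    n <- sample(4:25, 1)
    s <- sample(1:8, n, replace = TRUE)  # many ties
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auroc(s, l), oracle_auroc(s, l))
  }
})

test_that("AUROC of a monotone single-predictor model equals the raw predictor's", {
  set.seed(35)
  x <- rnorm(30)
  y <- rbinom(30, 1, plogis(2 * x))
  f <- firth_logistic_fit(cbind(1, x), y)
  expect_equal(auroc(f$fitted, y), auroc(x, y))
})

test_that("stratified bootstrap CI is reproducible, sane and narrows with n", {
  scores <- c(1, 2, 3, 4, 10, 11, 12, 13)
  labels <- rep(c(0, 1), each = 4)
  ci <- bootstrap_auroc_ci(scores, labels, n_boot = 200, seed = 5)
  expect_identical(ci, bootstrap_auroc_ci(scores, labels, n_boot = 200,
                                          seed = 5))
  expect_equal(ci$lo, 1)  # perfectly separated: every replicate separable
  expect_equal(ci$hi, 1)

  set.seed(36)
  small_s <- c(rnorm(17), rnorm(17, 1.2))
  small_l <- rep(0:1, each = 17)
  big_s <- c(rnorm(170), rnorm(170, 1.2))
  big_l <- rep(0:1, each = 170)
  ci_small <- bootstrap_auroc_ci(small_s, small_l, n_boot = 1000, seed = 6)
  ci_big <- bootstrap_auroc_ci(big_s, big_l, n_boot = 1000, seed = 6)
  expect_lt(ci_big$hi - ci_big$lo, ci_small$hi - ci_small$lo)
  # percentile interval brackets the point estimate (up to resampling noise)
  a <- auroc(small_s, small_l)
  expect_lte(ci_small$lo, a + 0.02)
  expect_gte(ci_small$hi, a - 0.02)
})

test_that("operating point maximizes the selection criterion over all cuts", {
  sep <- operating_point(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)

  # tie in Youden resolved toward higher sensitivity
  op <- operating_point(c(4, 3, 2, 1), c(1, 0, 1, 0))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 0.5)

  # exhaustive scan oracle on random data, all three rules
  set.seed(37)
  for (rule in c("youden", "closest_topleft")) {
    for (trial in 1:20) {
      s <- sample(1:10, 12, replace = TRUE)
      l <- c(0, 1, rbinom(10, 1, 0.5))
      op <- operating_point(s, l, rule = rule)
      crit <- function(th) {
        sens <- sum(s[l == 1] >= th) / sum(l == 1)
        spec <- sum(s[l == 0] < th) / sum(l == 0)
        if (rule == "youden") sens + spec - 1
        else -((1 - sens)^2 + (1 - spec)^2)
      }
      best <- max(vapply(c(s - 0.5, max(s) + 0.5), crit, numeric(1)))
      got_sens <- sum(s[l == 1] >= op$threshold) / sum(l == 1)
      got_spec <- sum(s[l == 0] < op$threshold) / sum(l == 0)
      got <- if (rule == "youden") got_sens + got_spec - 1 else
        -((1 - got_sens)^2 + (1 - got_spec)^2)
      expect_equal(got, best)
    }
  }

  # 14/17 correct in each class: Wilson CC bounds (0.56, 0.95)
  s14 <- c(rep(0, 14), rep(1, 3), rep(1, 14), rep(0, 3))
  l14 <- rep(c(0, 1), each = 17)
  op14 <- operating_point(s14, l14)
  expect_equal(op14$sensitivity, 14 / 17)
  expect_equal(round(op14$sensitivity_ci$lo, 2), 0.56)
  expect_equal(round(op14$sensitivity_ci$hi, 2), 0.95)
})

test_that("model panel: planted effect, null permutation and nesting", {
  sim <- generate_cohort(seed = 41)
  tal <- tabulate_all_episodes(sim$infections,
                               patient_ids = sim$patients$patient_id)
  sc <- severity_scores(sim$patients)
  dat <- data.frame(
    hypersusceptible = tal$hypersusceptible[
      match(sim$patients$patient_id, tal$patient_id)],
    ratio = ratio_series(sim$patients)$ratio,
    tbsa = sim$patients$tbsa, apacheii = sc$apacheii,
    baux = sc$baux, rbaux = sc$rbaux)
  models <- fit_roc_models(dat, n_boot = 300, seed = 42)
  expect_equal(nrow(models), 9)
  expect_true(all(models$converged))
  fits <- attr(models, "fits")
  expect_lt(fits$ratio$coefficients["ratio"], 0)  # lower ratio -> case
  expect_gt(models$auroc[models$model == "ratio"], 0.5)
  expect_true(all(models$ci_lo <= models$auroc + 1e-9 &
                    models$auroc <= models$ci_hi + 1e-9))

  # nesting: combined model's apparent AUROC >= its single components - eps
  eps <- 0.02
  for (m in c("tbsa", "apacheii", "baux", "rbaux")) {
    combined <- models$auroc[models$model == paste0("ratio+", m)]
    expect_gte(combined, models$auroc[models$model == m] - eps)
    expect_gte(combined, models$auroc[models$model == "ratio"] - eps)
  }

  # permuted outcome: apparent AUROCs collapse toward chance
  dat_null <- dat
  set.seed(43)
  dat_null$hypersusceptible <- sample(dat$hypersusceptible)
  null_models <- fit_roc_models(dat_null, n_boot = 100, seed = 44)
  expect_lt(mean(null_models$auroc[1:5]), 0.72)
})

test_that("ratio-model apparent AUROC lands in the published interval for most seeds", {
  hits <- 0
  n_seeds <- 120
  for (s in seq_len(n_seeds)) {
    sim <- generate_cohort(seed = 50000 + s)
    y <- as.numeric(sim$truth$group == "case")
    r <- ratio_series(sim$patients)$ratio
    f <- firth_logistic_fit(cbind(1, r), y)
    a <- auroc(f$fitted, y)
    hits <- hits + (a >= 0.63 && a <= 0.93)
  }
  expect_gte(hits / n_seeds, 0.75)
})
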