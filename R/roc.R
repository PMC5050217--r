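# ROC machinery: the Mann-Whitney AUROC estimator, stratified-bootstrap
# percentile confidence intervals, and operating-point selection with
# Wilson continuity-corrected intervals on sensitivity and specificity.

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen case receives a higher score than
#' a randomly chosen non-case, with ties counted one half — computed via
#' midranks, which is exactly the pairwise-counting estimator.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE = case).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified-bootstrap confidence interval for the AUROC
#'
#' Cases and non-cases are resampled independently with replacement
#' (stratified bootstrap), the AUROC recomputed on each replicate, and the
#' percentile bounds returned. Stratification guarantees every replicate
#' contains both classes.
#'
#' @inheritParams auroc
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer RNG seed; recorded in the result so intervals are
#'   bit-reproducible.
#' @param level Confidence level (default 0.95).
#' @return A list with `lo`, `hi`, `level`, `n_boot`, `seed` and the vector
#'   of replicate AUROCs as attribute `"replicates"`.
#' @export
bootstrap_auroc_ci <- function(scores, labels, n_boot = 10000, seed = 1,
                               level = 0.95) {
  labels <- as.logical(labels)
  case_idx <- which(labels)
  ctrl_idx <- which(!labels)
  stopifnot(length(case_idx) >= 2, length(ctrl_idx) >= 2)
  reps <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ci <- sample(case_idx, length(case_idx), replace = TRUE)
      ni <- sample(ctrl_idx, length(ctrl_idx), replace = TRUE)
      idx <- c(ci, ni)
      auroc(scores[idx], labels[idx])
    }, numeric(1))
  })
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(lo = qs[1], hi = qs[2], level = level, n_boot = n_boot,
                 seed = seed),
            replicates = reps)
}

#' ROC operating point with binomial confidence intervals
#'
#' Scans every achievable cut (midpoints between adjacent distinct scores,
#' plus the extremes) predicting "case" for scores at or above the
#' threshold, and picks the operating point by `rule`:
#' * `"youden"` (default): maximize sensitivity + specificity - 1; ties go
#'   to the threshold with higher sensitivity.
#' * `"closest_topleft"`: minimize (1 - sens)^2 + (1 - spec)^2.
#' * `"max_sens"`: highest sensitivity subject to specificity > 0.
#'
#' Sensitivity and specificity carry Wilson continuity-corrected intervals.
#'
#' @inheritParams auroc
#' @param rule Selection rule, see above.
#' @param level Confidence level for the Wilson intervals.
#' @return A list with `threshold`, `sensitivity`, `specificity`,
#'   `sensitivity_ci` and `specificity_ci` (each a [wilson_ci_cc()] result),
#'   and the selection `rule`.
#' @export
operating_point <- function(scores, labels,
                            rule = c("youden", "closest_topleft", "max_sens"),
                            level = 0.95) {
  rule <- match.arg(rule)
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  s <- sort(unique(scores))
  thresholds <- c(s[1] - 1, s[-length(s)] + diff(s) / 2, s[length(s)] + 1)
  sens <- vapply(thresholds, function(t) sum(scores[labels] >= t) / n1,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores[!labels] < t) / n0,
                 numeric(1))
  crit <- switch(rule,
                 youden = sens + spec - 1,
                 closest_topleft = -((1 - sens)^2 + (1 - spec)^2),
                 max_sens = ifelse(spec > 0, sens, -Inf))
  best <- which(crit == max(crit))
  if (length(best) > 1) best <- best[which.max(sens[best])]
  list(threshold = thresholds[best],
       sensitivity = sens[best],
       specificity = spec[best],
       sensitivity_ci = wilson_ci_cc(round(sens[best] * n1), n1, level),
       specificity_ci = wilson_ci_cc(round(spec[best] * n0), n0, level),
       rule = rule)
}

#' Fit the panel of hypersusceptibility prediction models
#'
#' Fits nine Firth-penalized logistic models for the hypersusceptibility
#' outcome: five single-predictor models (TNF-alpha/IL-10 ratio, TBSA,
#' APACHEII, Baux, R-Baux) and four two-predictor models combining the
#' ratio with each clinical score. For each model the in-sample (apparent)
#' AUROC of the fitted case probabilities is reported with a
#' stratified-bootstrap percentile CI and a Youden-rule operating point
#' whose sensitivity/specificity carry Wilson continuity-corrected CIs.
#' The ratio enters on its raw scale; because lower ratios predict cases
#' the fitted slope is negative, and the AUROC is computed from predicted
#' probabilities, so no manual sign flip is needed.
#'
#' @param data Data frame with columns `hypersusceptible` (logical or 0/1),
#'   `ratio`, `tbsa`, `apacheii`, `baux`, `rbaux`.
#' @param n_boot Bootstrap replicates per model (default 10000).
#' @param seed Integer RNG seed (per-model seeds are derived from it).
#' @param rule Operating-point rule passed to [operating_point()].
#' @return A `data.frame` with one row per model: `model`, `predictors`,
#'   `auroc`, `ci_lo`, `ci_hi`, `threshold`, `sensitivity`, `sens_lo`,
#'   `sens_hi`, `specificity`, `spec_lo`, `spec_hi`, `converged`, `n_boot`,
#'   `seed`. The fitted `firth_fit` objects are attached as attribute
#'   `"fits"`.
#' @export
fit_roc_models <- function(data, n_boot = 10000, seed = 1, rule = "youden") {
  needed <- c("hypersusceptible", "ratio", "tbsa", "apacheii", "baux", "rbaux")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  y <- as.numeric(data$hypersusceptible)
  if (length(unique(y)) < 2) stop("outcome must include cases and non-cases")
  specs <- list(
    "ratio" = "ratio",
    "tbsa" = "tbsa",
    "apacheii" = "apacheii",
    "baux" = "baux",
    "rbaux" = "rbaux",
    "ratio+tbsa" = c("ratio", "tbsa"),
    "ratio+apacheii" = c("ratio", "apacheii"),
    "ratio+baux" = c("ratio", "baux"),
    "ratio+rbaux" = c("ratio", "rbaux")
  )
  fits <- list()
  rows <- lapply(seq_along(specs), function(i) {
    preds <- specs[[i]]
    X <- cbind("(Intercept)" = 1, as.matrix(data[preds]))
    fit <- firth_logistic_fit(X, y)
    fits[[names(specs)[i]]] <<- fit
    scores <- fit$fitted
    a <- auroc(scores, y)
    ci <- bootstrap_auroc_ci(scores, y, n_boot = n_boot, seed = seed + i)
    op <- operating_point(scores, y, rule = rule)
    data.frame(model = names(specs)[i],
               predictors = paste(preds, collapse = "+"),
               auroc = a, ci_lo = ci$lo, ci_hi = ci$hi,
               threshold = op$threshold,
               sensitivity = op$sensitivity,
               sens_lo = op$sensitivity_ci$lo, sens_hi = op$sensitivity_ci$hi,
               specificity = op$specificity,
               spec_lo = op$specificity_ci$lo, spec_hi = op$specificity_ci$hi,
               converged = fit$converged, n_boot = n_boot, seed = seed + i,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
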