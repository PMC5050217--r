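# The TNF-alpha/IL-10 plasma cytokine ratio: a dimensionless measure of the
# pro- versus anti-inflammatory balance shortly after injury, plus the
# standardization and stratification machinery used to compare it across
# severity strata.

#' TNF-alpha/IL-10 ratio
#'
#' Ratio of plasma TNF-alpha to IL-10 concentration, both in pg/mL
#' (dimensionless). How concentrations below the assay detection limit are
#' handled is the caller's policy; here a zero or negative IL-10 is an
#' error, see `il10_lod` in [ratio_series()] for the substitution option.
#'
#' @param tnf_pg_ml TNF-alpha concentration, pg/mL (> 0).
#' @param il10_pg_ml IL-10 concentration, pg/mL (> 0).
#' @return Numeric ratio(s).
#' @export
tnf_il10_ratio <- function(tnf_pg_ml, il10_pg_ml) {
  if (any(il10_pg_ml <= 0) || any(tnf_pg_ml < 0)) {
    stop("undefined ratio: IL-10 must be > 0 and TNF-alpha >= 0 ",
         "(below-detection handling is the caller's policy)")
  }
  tnf_pg_ml / il10_pg_ml
}

#' Per-patient cytokine ratio series with z-scores
#'
#' Computes the TNF-alpha/IL-10 ratio for every patient and standardizes it
#' over the series (sample mean 0, sample SD 1, denominator n - 1).
#'
#' @param patients Patient table with `tnf_pg_ml` and `il10_pg_ml` columns.
#' @param il10_lod Optional assay detection limit for IL-10 (pg/mL). When
#'   given, IL-10 values of 0 are replaced by `il10_lod / 2` before the
#'   ratio is formed; when `NULL` (default) a zero IL-10 is an error.
#' @return A `data.frame` with columns `patient_id`, `ratio`, `zscore`.
#' @export
ratio_series <- function(patients, il10_lod = NULL) {
  il10 <- patients$il10_pg_ml
  if (!is.null(il10_lod)) il10[il10 == 0] <- il10_lod / 2
  ratio <- tnf_il10_ratio(patients$tnf_pg_ml, il10)
  z <- if (length(ratio) >= 2 && stats::sd(ratio) > 0) {
    (ratio - mean(ratio)) / stats::sd(ratio)
  } else {
    rep(NA_real_, length(ratio))
  }
  data.frame(patient_id = patients$patient_id, ratio = ratio, zscore = z,
             stringsAsFactors = FALSE)
}

#' Sort patients by ratio z-score
#'
#' Standardizes the ratio series by its sample mean and SD and returns the
#' patients in ascending z-score order (the most immunosuppressed first);
#' ties are broken by patient id so the order is deterministic.
#'
#' @param series Result of [ratio_series()] (or any data frame with
#'   `patient_id` and `ratio` columns).
#' @return The series, re-standardized, sorted ascending by z-score.
#' @export
zscore_sort <- function(series) {
  if (nrow(series) < 2) stop("need at least 2 patients to standardize")
  s <- stats::sd(series$ratio)
  if (s == 0) stop("constant ratio series has no z-scores")
  series$zscore <- (series$ratio - mean(series$ratio)) / s
  series[order(series$zscore, series$patient_id), , drop = FALSE]
}

#' Stratify patients on a numeric or categorical variable
#'
#' Three schemes are supported:
#' * `"mean"`: a two-level split at the floor of the sample mean, so the
#'   printed integer cutpoints are reproduced (e.g. a mean TBSA of 41.6
#'   splits at "<= 41" versus ">= 42"). Values `<= floor(mean(x))` form the
#'   lower stratum.
#' * `"quartile"`: four bins at Q1/median/Q3 computed with the
#'   linear-interpolation convention (`stats::quantile` type 7); ties go to
#'   the lower bin.
#' * `"category"`: `x` is used as-is (factor or character) — e.g. Ryan score
#'   values or [absi_category()] labels.
#'
#' @param x Per-patient stratification variable, named by patient id or
#'   accompanied by `patient_ids`.
#' @param scheme One of `"mean"`, `"quartile"`, `"category"`.
#' @param patient_ids Optional ids (defaults to `names(x)`).
#' @return A list of class `"stratification"` with `scheme`, `labels`
#'   (factor of stratum labels named by patient id) and `cutpoints` (where
#'   applicable). Strata always partition the patients.
#' @export
stratify <- function(x, scheme = c("mean", "quartile", "category"),
                     patient_ids = NULL) {
  scheme <- match.arg(scheme)
  ids <- patient_ids %||% names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  cutpoints <- NULL
  labels <- switch(scheme,
    mean = {
      if (length(x) < 2) stop("mean split needs >= 2 patients")
      cutpoints <- floor(mean(x))
      factor(ifelse(x <= cutpoints,
                    paste0("<=", cutpoints), paste0(">=", cutpoints + 1)),
             levels = c(paste0("<=", cutpoints), paste0(">=", cutpoints + 1)))
    },
    quartile = {
      if (length(x) < 4) stop("quartile split needs >= 4 patients")
      cutpoints <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7,
                                   names = FALSE)
      lab <- c("Q1", "Q2", "Q3", "Q4")
      bin <- 1L + (x > cutpoints[1]) + (x > cutpoints[2]) + (x > cutpoints[3])
      factor(lab[bin], levels = lab)
    },
    category = factor(x)
  )
  names(labels) <- ids
  structure(list(scheme = scheme, labels = labels, cutpoints = cutpoints),
            class = "stratification")
}

#' Summarize a variable within strata
#'
#' @param strata A [stratify()] result (or a factor named by patient id).
#' @param y Per-patient numeric variable to summarize (same order/names as
#'   the stratification input).
#' @return A `data.frame` with one row per stratum: `stratum`, `n`, `mean`,
#'   `sd`, `se` (`sd / sqrt(n)`). Empty strata are reported with `n = 0`
#'   and `NA` summaries.
#' @export
stratum_summary <- function(strata, y) {
  labels <- if (inherits(strata, "stratification")) strata$labels else strata
  out <- do.call(rbind, lapply(levels(labels), function(lv) {
    yy <- y[labels == lv]
    n <- sum(!is.na(yy))
    data.frame(stratum = lv, n = n,
               mean = if (n) mean(yy, na.rm = TRUE) else NA_real_,
               sd = if (n >= 2) stats::sd(yy, na.rm = TRUE) else NA_real_,
               se = if (n >= 2) stats::sd(yy, na.rm = TRUE) / sqrt(n)
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
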