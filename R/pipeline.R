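# End-to-end orchestration: baseline (Table-1-style) summaries, stratified
# ratio comparisons, the prediction-model panel, and the patient-by-pathogen
# matrix, all as machine-readable data frames.

fmt_mean_sd <- function(x) sprintf("%.3g ± %.3g", mean(x), stats::sd(x))
fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sprintf("%g [%g–%g]", q[2], q[1], q[3])
}
fmt_n_pct <- function(flag) {
  sprintf("%d (%.1f%%)", sum(flag), 100 * mean(flag))
}

.baseline_row <- function(variable, section, kind, all_v, non_v, case_v) {
  summarize <- switch(kind, continuous = fmt_mean_sd,
                      count = fmt_median_iqr, proportion = fmt_n_pct)
  p <- tryCatch(switch(kind,
    continuous = t_test_equal_var(non_v, case_v)$p_two_tailed,
    count = mann_whitney(non_v, case_v)$p_two_tailed,
    proportion = fisher_exact_2x2(rbind(
      c(sum(non_v), sum(!non_v)), c(sum(case_v), sum(!case_v))
    ))$p_two_tailed
  ), error = function(e) NA_real_)
  test <- switch(kind, continuous = "t-test", count = "mann-whitney",
                 proportion = "fisher")
  data.frame(section = section, variable = variable, kind = kind,
             overall = summarize(all_v), noncase = summarize(non_v),
             case = summarize(case_v), test = test, p = p,
             stringsAsFactors = FALSE)
}

#' Baseline characteristics table
#'
#' Builds a Table-1-style baseline table comparing hypersusceptible cases
#' (>= 3 episodes) with non-cases: continuous variables as mean +/- SD with
#' the equal-variance t-test, ordinal/count variables as median \[IQR\]
#' with the Mann-Whitney test, and proportions as n (%) with Fisher's exact
#' test (all two-tailed). The hospital-stay summary is restricted to
#' survivors. First-infection day is summarized among patients with at
#' least one recorded infection.
#'
#' @param patients Patient table (eligible cohort).
#' @param tallies Episode tally table from [tabulate_all_episodes()].
#' @param infections Infection table (for first-infection timing and
#'   per-type prevalences).
#' @return A `data.frame` with one row per variable: `section`, `variable`,
#'   `kind`, `overall`, `noncase`, `case`, `test`, `p`.
#' @export
run_baseline_table <- function(patients, tallies, infections) {
  m <- merge(patients, tallies, by = "patient_id", sort = FALSE)
  sc <- severity_scores(patients)
  m <- merge(m, sc[setdiff(names(sc), "apacheii")], by = "patient_id",
             sort = FALSE)
  rs <- ratio_series(patients)
  m <- merge(m, rs[c("patient_id", "ratio")], by = "patient_id", sort = FALSE)
  case <- m$hypersusceptible
  if (all(case) || !any(case)) {
    stop("baseline table needs both cases and non-cases")
  }
  cont <- function(variable, section, x) {
    .baseline_row(variable, section, "continuous", x, x[!case], x[case])
  }
  cnt <- function(variable, section, x) {
    .baseline_row(variable, section, "count", x, x[!case], x[case])
  }
  prop <- function(variable, section, flag) {
    .baseline_row(variable, section, "proportion", flag, flag[!case],
                  flag[case])
  }
  first_day <- tapply(infections$day, infections$patient_id, min)
  fd <- first_day[m$patient_id]
  has_inf <- !is.na(fd)
  inf_type <- function(ty) {
    ids <- unique(infections$patient_id[infections$itype == ty])
    m$patient_id %in% ids
  }
  surv <- !m$died
  rows <- list(
    cont("age_years", "demographics", m$age),
    prop("sex_male", "demographics", m$sex == "male"),
    cont("bmi", "demographics", m$bmi),
    cont("admission_delay_h", "demographics", m$admission_delay_h),
    prop("etiology_flame", "burn_injury", m$etiology == "flame"),
    prop("etiology_flash", "burn_injury", m$etiology == "flash"),
    prop("etiology_scald", "burn_injury", m$etiology == "scald"),
    prop("etiology_other", "burn_injury", m$etiology == "other"),
    cont("tbsa_pct", "burn_injury", m$tbsa),
    prop("second_degree", "burn_injury", m$second_degree),
    prop("third_degree", "burn_injury", m$third_degree),
    prop("inhalation", "burn_injury", m$inhalation),
    cont("apacheii", "burn_injury", m$apacheii),
    cont("baux", "burn_injury", m$baux),
    cont("rbaux", "burn_injury", m$rbaux),
    cnt("ryan", "burn_injury", m$ryan),
    cnt("absi", "burn_injury", m$absi),
    cont("blood_draw_h", "plasma", m$blood_draw_h),
    cont("tnf_il10_ratio", "plasma", m$ratio),
    .baseline_row("first_infection_day", "infections", "continuous",
                  fd[has_inf], fd[has_inf & !case], fd[has_inf & case]),
    cnt("n_infection_episodes", "infections", m$n_episodes),
    prop("burn_wound_infection", "infections", inf_type("burn wound")),
    prop("pneumonia", "infections", inf_type("pneumonia")),
    prop("bloodstream_infection", "infections", inf_type("bloodstream")),
    prop("urinary_tract_infection", "infections", inf_type("urinary tract")),
    prop("death", "outcomes", m$died),
    .baseline_row("hospital_days_survivors", "outcomes", "continuous",
                  m$hospital_days[surv], m$hospital_days[surv & !case],
                  m$hospital_days[surv & case])
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n") <- c(total = nrow(m), noncase = sum(!case),
                      case = sum(case))
  out
}

.strat_panel <- function(panel, labels, ratio) {
  s <- stratum_summary(labels, ratio)
  lv <- levels(labels)
  used <- lv[table(labels)[lv] >= 2]
  p <- NA_real_
  dunnett <- NULL
  if (length(used) == 2) {
    p <- t_test_equal_var(ratio[labels == used[1]],
                          ratio[labels == used[2]])$p_two_tailed
    test <- "t-test"
  } else if (length(used) > 2) {
    groups <- lapply(used, function(g) ratio[labels == g])
    names(groups) <- used
    res <- anova_dunnett(groups, reference_index = 1)
    p <- res$p_two_tailed
    dunnett <- res$dunnett
    test <- "anova+dunnett"
  } else {
    test <- "none"
  }
  s$panel <- panel
  s$test <- test
  s$p_overall <- p
  if (!is.null(dunnett)) {
    s$p_vs_first <- NA_real_
    for (i in seq_len(nrow(dunnett))) {
      g <- sub(" - .*$", "", dunnett$comparison[i])
      s$p_vs_first[s$stratum == g] <- dunnett$p_adjusted[i]
    }
  } else {
    s$p_vs_first <- NA_real_
  }
  s[c("panel", "stratum", "n", "mean", "sd", "se", "test", "p_overall",
      "p_vs_first")]
}

#' Stratified cytokine-ratio comparisons
#'
#' Reproduces the severity-stratified ratio panels: mean-split TBSA,
#' inhalation injury, full-thickness burn, mean-split APACHEII / Baux /
#' R-Baux (two-group equal-variance t-tests), Ryan score levels and ABSI
#' severity categories (one-way ANOVA with Dunnett comparisons against the
#' first category), plus quartile variants for TBSA and APACHEII. Strata
#' with fewer than 2 patients are reported but excluded from testing.
#'
#' @param patients Patient table (eligible cohort).
#' @return A `data.frame` with one row per (panel, stratum): per-stratum
#'   `n`, `mean`, `sd`, `se` of the ratio, the `test` used, the overall
#'   two-tailed `p_overall` and, for Dunnett panels, `p_vs_first`.
#' @export
run_severity_stratification <- function(patients) {
  rs <- ratio_series(patients)
  sc <- severity_scores(patients)
  stopifnot(identical(rs$patient_id, sc$patient_id))
  ratio <- rs$ratio
  ids <- rs$patient_id
  panels <- list(
    tbsa_mean = stratify(patients$tbsa, "mean", patient_ids = ids),
    tbsa_quartile = stratify(patients$tbsa, "quartile", patient_ids = ids),
    inhalation = stratify(ifelse(patients$inhalation, "yes", "no"),
                          "category", patient_ids = ids),
    third_degree = stratify(ifelse(patients$third_degree, "yes", "no"),
                            "category", patient_ids = ids),
    apacheii_mean = stratify(patients$apacheii, "mean", patient_ids = ids),
    apacheii_quartile = stratify(patients$apacheii, "quartile",
                                 patient_ids = ids),
    baux_mean = stratify(sc$baux, "mean", patient_ids = ids),
    rbaux_mean = stratify(sc$rbaux, "mean", patient_ids = ids),
    ryan = stratify(sc$ryan, "category", patient_ids = ids),
    absi = stratify(as.character(absi_category(sc$absi)), "category",
                    patient_ids = ids)
  )
  out <- do.call(rbind, lapply(names(panels), function(nm) {
    .strat_panel(nm, panels[[nm]]$labels, ratio)
  }))
  rownames(out) <- NULL
  out
}

#' Patient-by-pathogen matrix sorted by ratio z-score
#'
#' Rows are patients in ascending TNF-alpha/IL-10 ratio z-score order;
#' columns are the ratio z-score, the hypersusceptibility flag, z-scores of
#' the continuous severity scores (TBSA, APACHEII, Baux, R-Baux) and one
#' presence flag per pathogen ever isolated from the patient. Per-pathogen
#' overall prevalences are attached as attribute `"prevalence"`. The
#' apparent grouping of pathogens with hypersusceptibility status is a
#' consequence of this sorting, not of an algorithmic clustering.
#'
#' @param patients Patient table.
#' @param infections Infection table.
#' @param tallies Episode tally table from [tabulate_all_episodes()].
#' @return A `data.frame`, one row per patient.
#' @export
run_pathogen_matrix <- function(patients, infections, tallies) {
  rs <- zscore_sort(ratio_series(patients))
  sc <- severity_scores(patients)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  sc_z <- data.frame(patient_id = sc$patient_id,
                     tbsa_z = zs(patients$tbsa), apacheii_z = zs(sc$apacheii),
                     baux_z = zs(sc$baux), rbaux_z = zs(sc$rbaux),
                     stringsAsFactors = FALSE)
  out <- merge(rs, tallies[c("patient_id", "hypersusceptible")],
               by = "patient_id", sort = FALSE)
  out <- merge(out, sc_z, by = "patient_id", sort = FALSE)
  pathogens <- sort(unique(infections$pathogen))
  for (pg in pathogens) {
    ids <- unique(infections$patient_id[infections$pathogen == pg])
    out[[paste0("pathogen.", pg)]] <- as.integer(out$patient_id %in% ids)
  }
  out <- out[order(out$zscore, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  prevalence <- vapply(pathogens, function(pg) {
    mean(out[[paste0("pathogen.", pg)]])
  }, numeric(1))
  attr(out, "prevalence") <- prevalence
  out
}

#' Run the full analysis pipeline
#'
#' Eligibility screening, episode tabulation, severity scores, the cytokine
#' ratio, the baseline table, stratified comparisons, the prediction-model
#' panel and the pathogen matrix, in one call. When `out_dir` is given, all
#' artifacts are written as CSV/JSON with a provenance block (seed, package
#' version, config echo); re-running with the same inputs and seed yields
#' byte-identical artifacts.
#'
#' @param patients Patient table ([read_patient_table()]).
#' @param infections Infection table ([read_infection_table()]).
#' @param policy Waiting-list policy for episode tabulation.
#' @param n_boot Bootstrap replicates for the model panel.
#' @param seed Integer RNG seed for the bootstrap.
#' @param out_dir Optional output directory.
#' @return A list of class `"burncohort_report"` with `eligibility`,
#'   `tallies`, `scores`, `ratios`, `baseline`, `stratification`, `models`,
#'   `pathogen_matrix`, `provenance`.
#' @export
run_analysis <- function(patients, infections,
                         policy = waiting_list_policy(),
                         n_boot = 10000, seed = 1, out_dir = NULL) {
  elig <- apply_eligibility(patients, infections)
  pats <- patients[patients$patient_id %in% elig$eligible, , drop = FALSE]
  infs <- infections[infections$patient_id %in% elig$eligible, , drop = FALSE]
  message("eligibility: ", nrow(patients), " patients in, ",
          nrow(pats), " eligible")
  tallies <- tabulate_all_episodes(infs, patient_ids = pats$patient_id,
                                   policy = policy)
  scores <- severity_scores(pats)
  ratios <- ratio_series(pats)
  baseline <- run_baseline_table(pats, tallies, infs)
  strat <- run_severity_stratification(pats)
  model_data <- data.frame(
    hypersusceptible = tallies$hypersusceptible[
      match(pats$patient_id, tallies$patient_id)],
    ratio = ratios$ratio, tbsa = pats$tbsa, apacheii = scores$apacheii,
    baux = scores$baux, rbaux = scores$rbaux
  )
  models <- fit_roc_models(model_data, n_boot = n_boot, seed = seed)
  pmat <- run_pathogen_matrix(pats, infs, tallies)
  report <- structure(list(
    eligibility = elig, tallies = tallies, scores = scores, ratios = ratios,
    baseline = baseline, stratification = strat, models = models,
    pathogen_matrix = pmat,
    provenance = list(seed = seed, n_boot = n_boot,
                      package_version = as.character(
                        utils::packageVersion("burncohort")),
                      policy = unclass(policy),
                      n_input = nrow(patients), n_eligible = nrow(pats))),
    class = "burncohort_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report A `burncohort_report` from [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) {
    utils::write.csv(df, file.path(out_dir, f), row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  write_eligibility_report(report$eligibility,
                           file.path(out_dir, "eligibility.json"))
  w(report$tallies, "episodes.csv")
  assign_json <- lapply(attr(report$tallies, "tallies"), function(t) {
    as.list(t$assignment)
  })
  jsonlite::write_json(assign_json, file.path(out_dir, "episode_audit.json"),
                       auto_unbox = TRUE)
  w(report$scores, "scores.csv")
  w(report$ratios, "biomarker.csv")
  w(report$baseline, "baseline_table.csv")
  w(report$stratification, "stratified_ratio.csv")
  w(report$models, "models.csv")
  w(report$pathogen_matrix, "pathogen_matrix.csv")
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.burncohort_report <- function(x, ...) {
  cat("burncohort analysis report\n")
  cat("  eligible patients: ", x$provenance$n_eligible, " of ",
      x$provenance$n_input, "\n", sep = "")
  cat("  cases (>=3 episodes): ", sum(x$tallies$hypersusceptible), "\n",
      sep = "")
  cat("  models fitted: ", nrow(x$models), "\n", sep = "")
  invisible(x)
}
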