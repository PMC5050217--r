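# Burn severity scores. All calculators are vectorized over patients.
#
# Baux     = TBSA% + age
# R-Baux   = Baux + 17 if inhalation injury
# Ryan     = number of risk factors among {TBSA > 40%, age > 60, inhalation}
# ABSI     = sex point + inhalation point + full-thickness point
#            + age-category points + TBSA-category points

#' Ryan score
#'
#' One point for each risk factor present: TBSA strictly above 40%, age
#' strictly above 60 years, and inhalation injury.
#'
#' @param tbsa Burned body surface, percent (0-100).
#' @param age Age in years.
#' @param inhalation Logical, inhalation injury present.
#' @return Integer score in 0..3.
#' @export
ryan_score <- function(tbsa, age, inhalation) {
  assert_flag_vec(inhalation, "inhalation")
  as.integer((tbsa > 40) + (age > 60) + inhalation)
}

#' Abbreviated Burn Severity Index (ABSI)
#'
#' One point for male sex, one for inhalation injury, one for the presence
#' of full-thickness (third-degree) burn, plus age-category points (1 point
#' for ages 0-20 years, 2 for 21-40, and so on in 20-year steps) and
#' TBSA-category points (1 point for 1-10%, 2 for 11-20%, and so on in 10%
#' steps). Fractional values bucket by half-open intervals matching the
#' integer category labels: age points = `max(1, ceiling(age / 20))` (so age
#' 20.5 lands in the 21-40 bucket), TBSA points = `max(1, ceiling(tbsa / 10))`
#' for `tbsa >= 1`, and 0 points for `tbsa < 1` (an extension below the
#' published table; burns in this population start at 20% TBSA). Categories
#' continue unbounded in the same steps.
#'
#' @param sex `"male"` or `"female"`.
#' @param inhalation Logical, inhalation injury present.
#' @param third_degree Logical, full-thickness burn present.
#' @param age Age in years.
#' @param tbsa Burned body surface, percent.
#' @return Integer score.
#' @export
absi_score <- function(sex, inhalation, third_degree, age, tbsa) {
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  assert_flag_vec(inhalation, "inhalation")
  assert_flag_vec(third_degree, "third_degree")
  age_pts <- pmax(1L, as.integer(ceiling(age / 20)))
  tbsa_pts <- ifelse(tbsa < 1, 0L, pmax(1L, as.integer(ceiling(tbsa / 10))))
  as.integer((sex == "male") + inhalation + third_degree + age_pts + tbsa_pts)
}

#' ABSI severity category
#'
#' Reporting categories for the ABSI score: "moderately_severe" for 6-7,
#' "serious" for 8-9, "severe" for 10-11 and "maximum" for 12 or above;
#' scores of 5 or less are reported as "low".
#'
#' @param absi Integer ABSI score(s).
#' @return Ordered factor with the five category levels.
#' @export
absi_category <- function(absi) {
  cut(absi, breaks = c(-Inf, 5, 7, 9, 11, Inf),
      labels = c("low", "moderately_severe", "serious", "severe", "maximum"),
      ordered_result = TRUE)
}

#' Baux score
#'
#' Sum of TBSA percent and age in years.
#'
#' @inheritParams ryan_score
#' @return Numeric score.
#' @export
baux_score <- function(tbsa, age) {
  tbsa + age
}

#' Revised (modified) Baux score
#'
#' The Baux score plus 17 points for patients with inhalation injury.
#'
#' @inheritParams ryan_score
#' @return Numeric score.
#' @export
rbaux_score <- function(tbsa, age, inhalation) {
  assert_flag_vec(inhalation, "inhalation")
  baux_score(tbsa, age) + 17 * inhalation
}

#' Severity scores for a patient table
#'
#' Computes Ryan, ABSI, Baux and R-Baux for every patient and passes the
#' recorded APACHEII score through unchanged (APACHEII is an input recorded
#' at the treating institution, never computed here).
#'
#' @param patients Patient table ([read_patient_table()]).
#' @return A `data.frame` with columns `patient_id`, `ryan`, `absi`, `baux`,
#'   `rbaux`, `apacheii`.
#' @export
severity_scores <- function(patients) {
  data.frame(
    patient_id = patients$patient_id,
    ryan = ryan_score(patients$tbsa, patients$age, patients$inhalation),
    absi = absi_score(patients$sex, patients$inhalation,
                      patients$third_degree, patients$age, patients$tbsa),
    baux = baux_score(patients$tbsa, patients$age),
    rbaux = rbaux_score(patients$tbsa, patients$age, patients$inhalation),
    apacheii = patients$apacheii,
    stringsAsFactors = FALSE
  )
}
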