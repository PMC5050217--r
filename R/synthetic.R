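# Synthetic case-control cohort generator. Group-wise distributions are
# moment-matched to the published baseline table of the 34-patient burn
# cohort (17 hypersusceptible cases with >= 3 infection episodes, 17
# non-cases), so the full pipeline can be exercised and tested without the
# study's non-public patient-level data. Positive right-skewed quantities
# (cytokine ratio, IL-10) use log-normals matched to the printed mean/SD;
# bounded quantities use truncated normals.

#' Pathogen prevalence table
#'
#' Overall prevalence (fraction of patients with at least one isolate of
#' the microbe) used to sample pathogen labels in the synthetic generator;
#' the `unknown` label never matches in the episode similarity rule.
#'
#' @return A `data.frame` with `pathogen` and `prevalence` columns.
#' @export
pathogen_prevalences <- function() {
  data.frame(
    pathogen = c("enterococcus", "coagulase-negative staphylococci",
                 "s. aureus", "candida", "p. aeruginosa",
                 "gram-positive nos", "gram-negative nos", "acinetobacter",
                 "e. coli", "k. pneumoniae", "s. viridans", "fungi nos",
                 "s. pneumoniae", "h. influenza", "enterobacter", "unknown",
                 "aspergillus", "clostridium", "stenotrophomonas", "proteus"),
    prevalence = c(0.500, 0.471, 0.441, 0.353, 0.265, 0.265, 0.265, 0.235,
                   0.235, 0.235, 0.206, 0.206, 0.176, 0.147, 0.118, 0.088,
                   0.059, 0.059, 0.059, 0.029),
    stringsAsFactors = FALSE
  )
}

.itypes <- c("pneumonia", "bloodstream", "urinary tract", "burn wound",
             "endocarditis", "pseudomembranous colitis",
             "catheter-related bloodstream", "other")

#' Synthetic cohort configuration
#'
#' Defaults reproduce the group-level structure of the published cohort:
#' 17 cases / 17 non-cases; per-group TNF-alpha/IL-10 ratio log-normals
#' moment-matched to 0.067 +/- 0.072 (cases) and 0.200 +/- 0.154
#' (non-cases); per-group truncated-normal TBSA (51.2 +/- 20.0 vs
#' 31.9 +/- 11.2 on \[20, 100\]); age 40.6 +/- 17.2 on \[16, 90\]; per-group
#' inhalation probabilities 10/17 vs 5/17; blood draw time 19.9 +/- 12.0 h
#' on (0, 48\]; APACHEII 23.8 +/- 5.2 vs 14.1 +/- 7.8; first infection day
#' 5.4 +/- 3.0 truncated above 1 day (and above draw + 24 h so every
#' generated patient is eligible by construction). Case episode counts are
#' 3 + negative binomial (size 2.5, mean 4), giving median 6 with quartiles
#' near \[5, 10\]; non-case counts are drawn from \{0, 1, 2\} with
#' probabilities (0.30, 0.40, 0.30), giving median 1 \[0-2\].
#'
#' @param n_cases,n_noncases Group sizes (each >= 2).
#' @param ... Overrides for any default component (see the function body
#'   for names, e.g. `ratio_case = c(mean = ..., sd = ...)`).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_cases = 17, n_noncases = 17, ...) {
  cfg <- list(
    n_cases = n_cases,
    n_noncases = n_noncases,
    ratio_case = c(mean = 0.067, sd = 0.072),
    ratio_noncase = c(mean = 0.200, sd = 0.154),
    il10_meanlog = log(20), il10_sdlog = 0.9,
    tbsa_case = c(mean = 51.2, sd = 20.0),
    tbsa_noncase = c(mean = 31.9, sd = 11.2),
    tbsa_support = c(20, 100),
    age = c(mean = 40.6, sd = 17.2),
    age_support = c(16, 90),
    bmi = c(mean = 26.3, sd = 6.9),
    bmi_support = c(15, 60),
    p_male_case = 10 / 17, p_male_noncase = 12 / 17,
    p_inhalation_case = 10 / 17, p_inhalation_noncase = 5 / 17,
    p_third_case = 17 / 17, p_third_noncase = 14 / 17,
    p_second_case = 14 / 17, p_second_noncase = 13 / 17,
    etiology_p_case = c(flame = 13, flash = 3, scald = 0, other = 1) / 17,
    etiology_p_noncase = c(flame = 10, flash = 2, scald = 2, other = 3) / 17,
    apacheii_case = c(mean = 23.8, sd = 5.2),
    apacheii_noncase = c(mean = 14.1, sd = 7.8),
    apacheii_support = c(0, 71),
    admission_h_case = c(mean = 4.4, sd = 2.3),
    admission_h_noncase = c(mean = 3.9, sd = 2.7),
    admission_support = c(0.1, 24),
    draw_h = c(mean = 19.9, sd = 12.0),
    draw_support = c(0.5, 48),
    first_infection_day = c(mean = 5.4, sd = 3.0),
    episodes_noncase_p = c("0" = 0.30, "1" = 0.40, "2" = 0.30),
    episodes_case_nb = c(size = 2.5, mu = 4),
    p_death_case = 5 / 17, p_death_noncase = 1 / 17,
    hospital_days_case = c(mean = 92.2, sd = 63.7),
    hospital_days_noncase = c(mean = 27.2, sd = 15.4),
    icu_days_case = c(mean = 40, sd = 25),
    icu_days_noncase = c(mean = 15, sd = 10)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$n_cases < 2 || cfg$n_noncases < 2) {
    stop("config error: need at least 2 patients per group")
  }
  for (nm in c("ratio_case", "ratio_noncase")) {
    if (any(cfg[[nm]] <= 0)) stop("config error: ", nm, " must be positive")
  }
  chk_trunc <- function(par, sup, nm) {
    if (par[["mean"]] < sup[1] - 4 * par[["sd"]] ||
        par[["mean"]] > sup[2] + 4 * par[["sd"]]) {
      stop("config error: infeasible truncation for ", nm,
           " (mean far outside support)")
    }
  }
  chk_trunc(cfg$tbsa_case, cfg$tbsa_support, "tbsa_case")
  chk_trunc(cfg$tbsa_noncase, cfg$tbsa_support, "tbsa_noncase")
  chk_trunc(cfg$age, cfg$age_support, "age")
  chk_trunc(cfg$bmi, cfg$bmi_support, "bmi")
  chk_trunc(cfg$draw_h, cfg$draw_support, "draw_h")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic burn cohort
#'
#' Deterministic under `(config, seed)`. TNF-alpha and IL-10 concentrations
#' are emitted separately — IL-10 is drawn log-normal and TNF-alpha is
#' reconstructed as ratio x IL-10 — so the downstream biomarker stage
#' computes the ratio rather than receiving it. Infection histories are
#' planted so that [tabulate_episodes()] recovers each patient's episode
#' count exactly under the generating policy, and every generated patient
#' passes [apply_eligibility()] by construction.
#'
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @param policy Waiting-list policy used when planting infection clusters.
#' @return A list with `patients` (patient table), `infections` (infection
#'   table) and `truth` (`patient_id`, `group`, `n_episodes` planted).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            policy = waiting_list_policy()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases + config$n_noncases
  is_case <- rep(c(FALSE, TRUE), c(config$n_noncases, config$n_cases))
  withr_seed(seed, {
    pick <- function(field) {
      cs <- config[[paste0(field, "_case")]]
      nc <- config[[paste0(field, "_noncase")]]
      list(case = cs, noncase = nc)
    }
    grp_truncnorm <- function(field, support) {
      p <- pick(field)
      out <- numeric(n)
      out[!is_case] <- rtruncnorm_matched(sum(!is_case),
                                          p$noncase[["mean"]],
                                          p$noncase[["sd"]],
                                          support[1], support[2])
      out[is_case] <- rtruncnorm_matched(sum(is_case), p$case[["mean"]],
                                         p$case[["sd"]],
                                         support[1], support[2])
      out
    }
    grp_bernoulli <- function(field) {
      p <- pick(field)
      stats::runif(n) < ifelse(is_case, p$case, p$noncase)
    }

    ids <- sprintf("P%03d", seq_len(n))
    mm_case <- lognormal_moments(config$ratio_case[["mean"]],
                                 config$ratio_case[["sd"]])
    mm_non <- lognormal_moments(config$ratio_noncase[["mean"]],
                                config$ratio_noncase[["sd"]])
    ratio <- numeric(n)
    ratio[!is_case] <- stats::rlnorm(sum(!is_case), mm_non[["meanlog"]],
                                     mm_non[["sdlog"]])
    ratio[is_case] <- stats::rlnorm(sum(is_case), mm_case[["meanlog"]],
                                    mm_case[["sdlog"]])
    il10 <- stats::rlnorm(n, config$il10_meanlog, config$il10_sdlog)
    tnf <- ratio * il10

    tbsa <- grp_truncnorm("tbsa", config$tbsa_support)
    age <- rtruncnorm_matched(n, config$age[["mean"]], config$age[["sd"]],
                              config$age_support[1], config$age_support[2])
    bmi <- rtruncnorm_matched(n, config$bmi[["mean"]], config$bmi[["sd"]],
                              config$bmi_support[1], config$bmi_support[2])
    sex <- ifelse(grp_bernoulli("p_male"), "male", "female")
    inhalation <- grp_bernoulli("p_inhalation")
    third <- grp_bernoulli("p_third")
    second <- grp_bernoulli("p_second")
    etiology <- character(n)
    etiology[!is_case] <- sample(names(config$etiology_p_noncase),
                                 sum(!is_case), TRUE,
                                 config$etiology_p_noncase)
    etiology[is_case] <- sample(names(config$etiology_p_case),
                                sum(is_case), TRUE, config$etiology_p_case)
    apache <- round(grp_truncnorm("apacheii", config$apacheii_support))
    admission <- grp_truncnorm("admission_h", config$admission_support)
    draw_h <- rtruncnorm_matched(n, config$draw_h[["mean"]],
                                 config$draw_h[["sd"]],
                                 config$draw_support[1],
                                 config$draw_support[2])
    died <- grp_bernoulli("p_death")
    hosp <- pmax(1, grp_truncnorm("hospital_days", c(1, 400)))
    icu <- pmax(1, grp_truncnorm("icu_days", c(1, 200)))

    n_episodes <- integer(n)
    n_episodes[!is_case] <- as.integer(sample(
      names(config$episodes_noncase_p), sum(!is_case), TRUE,
      config$episodes_noncase_p))
    n_episodes[is_case] <- 3L + stats::rnbinom(
      sum(is_case), size = config$episodes_case_nb[["size"]],
      mu = config$episodes_case_nb[["mu"]])

    infections <- vector("list", n)
    for (i in seq_len(n)) {
      if (n_episodes[i] == 0) next
      # first infection strictly later than 1 day post-burn AND at least
      # 24 h after the blood draw, so eligibility holds by construction
      lo_day <- max(1, hours_to_days(draw_h[i] + 24)) + 0.01
      first_day <- rtruncnorm(1, config$first_infection_day[["mean"]],
                              config$first_infection_day[["sd"]],
                              lo_day, Inf)
      infections[[i]] <- generate_infection_history(
        n_episodes[i], policy = policy, patient_id = ids[i],
        first_day = first_day)
    }
    infections <- do.call(rbind, infections[!vapply(infections, is.null,
                                                    logical(1))])
    if (is.null(infections)) {
      infections <- data.frame(patient_id = character(0), day = numeric(0),
                               itype = character(0), mode = character(0),
                               pathogen = character(0),
                               stringsAsFactors = FALSE)
    }

    patients <- data.frame(
      patient_id = ids, age = age, sex = sex, bmi = bmi, etiology = etiology,
      tbsa = tbsa, second_degree = second, third_degree = third,
      inhalation = inhalation, admission_delay_h = admission,
      blood_draw_h = draw_h, tnf_pg_ml = tnf, il10_pg_ml = il10,
      apacheii = as.integer(apache), icu_days = icu, died = died,
      hospital_days = hosp, stringsAsFactors = FALSE
    )
    truth <- data.frame(patient_id = ids,
                        group = ifelse(is_case, "case", "noncase"),
                        n_episodes = n_episodes, stringsAsFactors = FALSE)
    list(patients = validate_patient_table(patients),
         infections = infections, truth = truth)
  })
}

#' Plant an infection history with a known episode count
#'
#' Generates infection records forming exactly `n_episodes` clusters under
#' the given waiting-list policy: within a cluster, consecutive records are
#' at most `dissimilar_window` days apart (so they chain into one episode
#' whether or not the similarity rule fires), and consecutive clusters are
#' separated by strictly more than `similar_window` days from the previous
#' cluster's last record (so no record is still waiting). The round-trip
#' contract `tabulate_episodes(...)$n_episodes == n_episodes` holds for
#' every seed. Uses the current RNG state.
#'
#' @param n_episodes Number of independent episodes to plant (>= 0).
#' @param policy A [waiting_list_policy()].
#' @param patient_id Patient id stamped on the records.
#' @param first_day Day (since injury) of the first record.
#' @return An infection-table `data.frame` (possibly 0 rows).
#' @export
generate_infection_history <- function(n_episodes, policy =
                                         waiting_list_policy(),
                                       patient_id = "P001", first_day = 5) {
  stopifnot(n_episodes >= 0)
  if (n_episodes == 0) {
    return(data.frame(patient_id = character(0), day = numeric(0),
                      itype = character(0), mode = character(0),
                      pathogen = character(0), stringsAsFactors = FALSE))
  }
  prev <- pathogen_prevalences()
  sizes <- sample(1:3, n_episodes, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  itype_ep <- sample(.itypes, n_episodes, replace = TRUE)
  pathogen_ep <- sample(prev$pathogen, n_episodes, replace = TRUE,
                        prob = prev$prevalence)
  total <- sum(sizes)
  ep_of_record <- rep(seq_len(n_episodes), sizes)
  # gap to the previous record: within an episode at most the dissimilar
  # window (chains regardless of similarity), between episodes strictly
  # more than the similar window (never waits)
  first_of_ep <- !duplicated(ep_of_record)
  gaps <- stats::runif(total, 0.25, policy$dissimilar_window)
  gaps[first_of_ep] <- policy$similar_window + stats::runif(n_episodes,
                                                            0.5, 4)
  gaps[1] <- 0
  days <- first_day + cumsum(gaps)
  itype <- itype_ep[ep_of_record]
  data.frame(
    patient_id = patient_id, day = days, itype = itype,
    mode = ifelse(itype == "burn wound", "burn_wound", "nosocomial"),
    pathogen = pathogen_ep[ep_of_record], stringsAsFactors = FALSE)
}
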