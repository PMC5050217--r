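# Independent reference implementations ("oracles") used to cross-check the
# package's algorithms, plus small fixture builders. Oracles deliberately
# use different code structure from the implementation they check.

make_infections <- function(days, itype = "pneumonia", mode = "nosocomial",
                            pathogen = "s. aureus", patient_id = "P1") {
  data.frame(patient_id = patient_id, day = days,
             itype = rep_len(itype, length(days)),
             mode = rep_len(mode, length(days)),
             pathogen = rep_len(pathogen, length(days)),
             stringsAsFactors = FALSE)
}

make_patient <- function(patient_id = "P1", age = 40, sex = "male",
                         bmi = 25, etiology = "flame", tbsa = 40,
                         second_degree = TRUE, third_degree = TRUE,
                         inhalation = FALSE, admission_delay_h = 4,
                         blood_draw_h = 20, tnf_pg_ml = 5, il10_pg_ml = 50,
                         apacheii = 18L, icu_days = 10, died = FALSE,
                         hospital_days = 40) {
  data.frame(patient_id = patient_id, age = age, sex = sex, bmi = bmi,
             etiology = etiology, tbsa = tbsa,
             second_degree = second_degree, third_degree = third_degree,
             inhalation = inhalation, admission_delay_h = admission_delay_h,
             blood_draw_h = blood_draw_h, tnf_pg_ml = tnf_pg_ml,
             il10_pg_ml = il10_pg_ml, apacheii = apacheii,
             icu_days = icu_days, died = died,
             hospital_days = hospital_days, stringsAsFactors = FALSE)
}

no_infections <- function() {
  data.frame(patient_id = character(0), day = numeric(0),
             itype = character(0), mode = character(0),
             pathogen = character(0), stringsAsFactors = FALSE)
}

# --- episode tabulation oracle -------------------------------------------
# Naive transcription of the waiting-list rule keeping an explicit list of
# episodes, each holding the days and fields of its member records.
oracle_episodes <- function(records, policy = waiting_list_policy()) {
  n <- nrow(records)
  if (n == 0) return(list(n_episodes = 0L, assignment = integer(0)))
  ord <- order(records$day, seq_len(n), records$itype)
  episodes <- list()  # each: list(rows = indices into records)
  assignment <- integer(n)
  sim <- function(i, j) {
    for (f in policy$similarity_fields) {
      if (records[[f]][i] == "unknown" || records[[f]][j] == "unknown") {
        return(FALSE)
      }
      if (records[[f]][i] != records[[f]][j]) return(FALSE)
    }
    TRUE
  }
  for (idx in ord) {
    best_day <- -Inf
    best_ep <- NA_integer_
    for (e in seq_along(episodes)) {
      for (i in episodes[[e]]$rows) {
        win <- if (sim(i, idx)) policy$similar_window else
          policy$dissimilar_window
        if (records$day[idx] - records$day[i] <= win) {
          if (records$day[i] > best_day ||
              (records$day[i] == best_day && e < best_ep)) {
            best_day <- records$day[i]
            best_ep <- e
          }
        }
      }
    }
    if (is.na(best_ep)) {
      episodes[[length(episodes) + 1]] <- list(rows = idx)
      assignment[idx] <- length(episodes)
    } else {
      episodes[[best_ep]]$rows <- c(episodes[[best_ep]]$rows, idx)
      assignment[idx] <- best_ep
    }
  }
  list(n_episodes = length(episodes), assignment = assignment)
}

random_infection_records <- function(n, patient_id = "P1") {
  make_infections(
    days = round(stats::runif(n, 0, 25), 1),
    itype = sample(c("pneumonia", "uti", "bloodstream"), n, replace = TRUE),
    mode = sample(c("nosocomial", "burn_wound"), n, replace = TRUE),
    pathogen = sample(c("s. aureus", "e. coli", "unknown"), n,
                      replace = TRUE),
    patient_id = patient_id
  )
}

# --- ABSI table oracle ---------------------------------------------------
# Pure lookup-table version of the ABSI point allocation.
oracle_absi <- function(sex, inhalation, third_degree, age, tbsa) {
  age_breaks <- seq(0, 220, by = 20)   # 0-20 -> 1, 21-40 -> 2, ...
  age_pts <- as.integer(cut(age, breaks = c(-0.5, age_breaks[-1]),
                            labels = FALSE))
  tbsa_breaks <- seq(0, 110, by = 10)  # 1-10 -> 1, 11-20 -> 2, ...
  tbsa_pts <- ifelse(tbsa < 1, 0L,
                     as.integer(cut(tbsa, breaks = c(0.999, tbsa_breaks[-1]),
                                    labels = FALSE)))
  (sex == "male") + inhalation + third_degree + age_pts + tbsa_pts
}

# --- AUROC pairwise oracle -----------------------------------------------
oracle_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  cs <- scores[labels]
  ns <- scores[!labels]
  tot <- 0
  for (a in cs) for (b in ns) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cs) * length(ns))
}

# --- Firth penalized-likelihood oracle -----------------------------------
# Independent formulation of the penalized log-likelihood, maximized by
# general-purpose optimization (Nelder-Mead refined from several starts).
oracle_firth <- function(X, y, starts = list(rep(0, ncol(X)))) {
  X <- as.matrix(X)
  pll <- function(b) {
    eta <- drop(X %*% b)
    p <- 1 / (1 + exp(-eta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    w <- p * (1 - p)
    info <- t(X * w) %*% X
    sum(y * log(p) + (1 - y) * log(1 - p)) + 0.5 * log(det(info))
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, function(b) -pll(b), method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
    # polish: restart Nelder-Mead from the incumbent until it stalls
    for (r in 1:5) {
      o2 <- stats::optim(o$par, function(b) -pll(b), method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 20000))
      if (o$value - o2$value < 1e-12) { o <- o2; break }
      o <- o2
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  unname(best$par)
}

# --- textbook pooled t-test oracle ---------------------------------------
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tstat, p = 2 * pt(-abs(tstat), n1 + n2 - 2))
}
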