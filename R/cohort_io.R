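# Reading, validating and filtering the two tabular inputs:
#   patients.csv   one row per enrolled subject
#   infections.csv one row per recorded infection

#' Column names of a patient table
#'
#' @return Character vector of the required columns of `patients.csv`.
#' @export
patient_columns <- function() {
  c("patient_id", "age", "sex", "bmi", "etiology", "tbsa",
    "second_degree", "third_degree", "inhalation",
    "admission_delay_h", "blood_draw_h",
    "tnf_pg_ml", "il10_pg_ml", "apacheii",
    "icu_days", "died", "hospital_days")
}

#' Column names of an infection table
#'
#' @return Character vector of the required columns of `infections.csv`.
#' @export
infection_columns <- function() {
  c("patient_id", "day", "itype", "mode", "pathogen")
}

# Accepted spellings for categorical fields; everything is lower-cased first.
.sex_aliases <- c(
  male = "male", m = "male", man = "male",
  female = "female", f = "female", woman = "female"
)
.etiologies <- c("flame", "flash", "scald", "electrical", "other")

.parse_flag <- function(x, column) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[v %in% c("false", "f", "no", "n", "0")] <- FALSE
  if (anyNA(out[!is.na(v) & v != ""])) {
    bad <- unique(v[is.na(out) & !is.na(v) & v != ""])
    stop("column '", column, "': cannot interpret ", paste(bad, collapse = ", "),
         " as a yes/no flag")
  }
  as.logical(out)
}

.parse_num <- function(x, column) {
  v <- suppressWarnings(as.numeric(as.character(x)))
  bad <- which(is.na(v) & !is.na(x) & trimws(as.character(x)) != "")
  if (length(bad)) {
    stop("column '", column, "': malformed numeric value in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  v
}

#' Read and validate a patient table
#'
#' Reads a UTF-8 CSV with one row per subject, normalizes categorical fields
#' to lower case (`sex` accepts the aliases m/male/man and f/female/woman),
#' coerces yes/no flags to logical, and enforces basic invariants:
#' `patient_id` unique, `tbsa` in \[0, 100\], non-negative ages, timings and
#' cytokine concentrations.
#'
#' @param path Path to a CSV file with the columns of [patient_columns()].
#' @return A `data.frame`, one row per patient.
#' @seealso [write_patient_table()], [apply_eligibility()]
#' @export
read_patient_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  missing <- setdiff(patient_columns(), names(raw))
  if (length(missing)) {
    stop("patient table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_patient_table(normalize_patient_table(raw[patient_columns()]))
}

# Normalization shared by the reader and the synthetic generator.
normalize_patient_table <- function(df) {
  df$patient_id <- as.character(df$patient_id)
  sex <- tolower(trimws(as.character(df$sex)))
  unknown <- setdiff(unique(sex), names(.sex_aliases))
  if (length(unknown)) {
    stop("column 'sex': unrecognized value(s) ", paste(unknown, collapse = ", "))
  }
  df$sex <- unname(.sex_aliases[sex])
  df$etiology <- tolower(trimws(as.character(df$etiology)))
  bad_eti <- setdiff(unique(df$etiology), .etiologies)
  if (length(bad_eti)) {
    stop("column 'etiology': unrecognized value(s) ",
         paste(bad_eti, collapse = ", "))
  }
  for (col in c("age", "bmi", "tbsa", "admission_delay_h", "blood_draw_h",
                "tnf_pg_ml", "il10_pg_ml", "apacheii", "icu_days",
                "hospital_days")) {
    df[[col]] <- .parse_num(df[[col]], col)
  }
  df$apacheii <- as.integer(round(df$apacheii))
  for (col in c("second_degree", "third_degree", "inhalation", "died")) {
    df[[col]] <- .parse_flag(df[[col]], col)
  }
  df
}

validate_patient_table <- function(df) {
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  }
  chk <- function(cond, msg) {
    bad <- which(!cond & !is.na(cond))
    if (length(bad)) {
      stop(msg, " (patient ", paste(df$patient_id[utils::head(bad, 5)],
                                    collapse = ", "), ")")
    }
  }
  chk(df$tbsa >= 0 & df$tbsa <= 100, "tbsa must be within [0, 100]")
  chk(df$age >= 0, "age must be non-negative")
  chk(df$admission_delay_h >= 0, "admission_delay_h must be non-negative")
  chk(df$blood_draw_h >= 0, "blood_draw_h must be non-negative")
  chk(df$tnf_pg_ml >= 0, "tnf_pg_ml must be non-negative")
  chk(df$il10_pg_ml >= 0, "il10_pg_ml must be non-negative")
  rownames(df) <- NULL
  df
}

#' Write a patient table
#'
#' Inverse of [read_patient_table()]: a valid table round-trips through
#' write/read with identical fields.
#'
#' @param patients Data frame as returned by [read_patient_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(patients, path) {
  utils::write.csv(patients[patient_columns()], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate an infection table
#'
#' One row per recorded infection: `patient_id`, `day` (fractional days since
#' injury, day 0 = injury), `itype` (infection type), `mode` (burn-wound vs
#' nosocomial vs other, as recorded), `pathogen`. Missing or empty pathogen
#' labels are normalized to the literal category `"unknown"`.
#'
#' @param path Path to a CSV file with the columns of [infection_columns()].
#' @return A `data.frame`, one row per infection record.
#' @export
read_infection_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  missing <- setdiff(infection_columns(), names(raw))
  if (length(missing)) {
    stop("infection table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- raw[infection_columns()]
  df$patient_id <- as.character(df$patient_id)
  df$day <- .parse_num(df$day, "day")
  if (anyNA(df$day) || any(df$day < 0) || any(!is.finite(df$day))) {
    stop("column 'day': days since injury must be finite and >= 0")
  }
  for (col in c("itype", "mode", "pathogen")) {
    v <- tolower(trimws(as.character(df[[col]])))
    empty <- is.na(v) | v == ""
    if (any(empty)) {
      if (col == "pathogen") v[empty] <- "unknown"
      else stop("column '", col, "': empty value not allowed")
    }
    df[[col]] <- v
  }
  rownames(df) <- NULL
  df
}

#' Write an infection table
#'
#' @param infections Data frame as returned by [read_infection_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_infection_table <- function(infections, path) {
  utils::write.csv(infections[infection_columns()], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the study eligibility filter
#'
#' A patient is eligible iff all of the following hold: age >= 16 years;
#' etiology is not electrical; first blood draw within 48 h of injury;
#' either no infection was recorded or the first recorded infection occurred
#' at least 24 h after the blood draw (boundary equality counts as eligible);
#' at least one ICU day; and all required fields are present. Several
#' criteria can fail at once, so exclusion reasons are reported per patient
#' as a set.
#'
#' The 48-h window is measured from injury, not admission, and infection
#' timing is converted from days since injury to hours before comparison.
#' Patients with multiple blood draws are expected to be already reduced to
#' their earliest draw.
#'
#' @param patients Patient table ([read_patient_table()]).
#' @param infections Infection table ([read_infection_table()]); used only
#'   for the infection-timing criterion.
#' @param max_draw_h Latest permissible blood draw, hours since injury
#'   (default 48).
#' @param min_gap_h Minimum gap between draw and first infection, hours
#'   (default 24).
#' @param min_age Minimum age in years (default 16).
#' @return A list of class `"eligibility_report"` with elements `eligible`
#'   (character vector of patient ids) and `exclusions` (named list mapping
#'   each excluded patient id to its violated criteria). Every input patient
#'   appears in exactly one of the two.
#' @export
apply_eligibility <- function(patients, infections,
                              max_draw_h = 48, min_gap_h = 24, min_age = 16) {
  exclusions <- list()
  eligible <- character(0)
  first_day <- if (nrow(infections)) {
    tapply(infections$day, infections$patient_id, min)
  } else {
    numeric(0)
  }
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    reasons <- character(0)
    if (anyNA(p[patient_columns()])) reasons <- c(reasons, "missing_fields")
    if (!is.na(p$age) && p$age < min_age) reasons <- c(reasons, "age<16")
    if (!is.na(p$etiology) && p$etiology == "electrical") {
      reasons <- c(reasons, "electrical_burn")
    }
    if (!is.na(p$blood_draw_h) && p$blood_draw_h > max_draw_h) {
      reasons <- c(reasons, "draw>48h")
    }
    fd <- first_day[p$patient_id]
    if (!is.na(p$blood_draw_h) && length(fd) == 1 && !is.na(fd) &&
        days_to_hours(fd) < p$blood_draw_h + min_gap_h) {
      reasons <- c(reasons, "infection_before_draw+24h")
    }
    if (!is.na(p$icu_days) && p$icu_days < 1) reasons <- c(reasons, "icu<1d")
    if (length(reasons)) {
      exclusions[[p$patient_id]] <- reasons
    } else {
      eligible <- c(eligible, p$patient_id)
    }
  }
  structure(list(eligible = eligible, exclusions = exclusions),
            class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Eligibility report:", length(x$eligible), "eligible,",
      length(x$exclusions), "excluded\n")
  for (id in names(x$exclusions)) {
    cat("  ", id, ": ", paste(x$exclusions[[id]], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Write an eligibility report as JSON
#'
#' @param report Result of [apply_eligibility()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eligibility_report <- function(report, path) {
  jsonlite::write_json(
    list(eligible = report$eligible,
         exclusions = lapply(report$exclusions, as.list)),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
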