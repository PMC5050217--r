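# Tabulation of independent infection episodes by a waiting-list decision
# tree: each recorded infection keeps the episode "open" (waiting) for a
# number of days that depends on whether a subsequent record looks like the
# same infection (similar type, mode and pathogen) or a different one.

#' Waiting-list policy for episode tabulation
#'
#' A subsequent infection record is merged into an earlier record's episode
#' if it falls within `similar_window` days of that record when the two
#' records are similar, or within `dissimilar_window` days when they are not.
#' Similarity requires equality on all of `similarity_fields`; the literal
#' pathogen label `"unknown"` never matches anything, which conservatively
#' forces the short window.
#'
#' @param similar_window Days a record waits for a similar follow-up
#'   (default 6).
#' @param dissimilar_window Days a record waits for a dissimilar follow-up
#'   (default 2).
#' @param similarity_fields Record fields compared for similarity; any
#'   non-empty subset of `c("itype", "mode", "pathogen")` (default all
#'   three, i.e. type AND mode AND pathogen must agree).
#' @return A list of class `"waiting_list_policy"`.
#' @export
waiting_list_policy <- function(similar_window = 6, dissimilar_window = 2,
                                similarity_fields = c("itype", "mode",
                                                      "pathogen")) {
  stopifnot(similar_window > 0, dissimilar_window > 0,
            similar_window >= dissimilar_window)
  similarity_fields <- match.arg(similarity_fields,
                                 c("itype", "mode", "pathogen"),
                                 several.ok = TRUE)
  structure(list(similar_window = similar_window,
                 dissimilar_window = dissimilar_window,
                 similarity_fields = similarity_fields),
            class = "waiting_list_policy")
}

#' Are two infection records similar?
#'
#' @param a,b Single rows of an infection table (same patient).
#' @param policy A [waiting_list_policy()].
#' @return `TRUE` iff all `similarity_fields` are equal and none has the
#'   value `"unknown"`.
#' @export
infection_similar <- function(a, b, policy = waiting_list_policy()) {
  for (f in policy$similarity_fields) {
    if (a[[f]] == "unknown" || b[[f]] == "unknown") return(FALSE)
    if (a[[f]] != b[[f]]) return(FALSE)
  }
  TRUE
}

#' Tabulate independent infection episodes for one patient
#'
#' Records are processed in nondecreasing day order (ties broken by input
#' order, then by infection type). A previously processed record `r` is
#' still "waiting" for a candidate `c` iff
#' `c$day - r$day <= similar_window` when `infection_similar(r, c)` holds,
#' or `<= dissimilar_window` otherwise (boundary equality extends). If any
#' prior record is waiting, the candidate joins the episode of the most
#' recent such record (ties broken toward the lowest episode index);
#' otherwise it opens a new episode. Every joining record re-arms its
#' episode's window (its own day becomes a fresh anchor), so an episode can
#' be extended indefinitely by a chain of records.
#'
#' @param records Infection table rows for a single patient.
#' @param policy A [waiting_list_policy()].
#' @return A list of class `"episode_tally"` with `patient_id`,
#'   `n_episodes`, and `assignment`: an integer vector mapping each input
#'   row (in input order) to its episode index. Episode indices are
#'   contiguous, starting at 1, numbered in onset order.
#' @export
tabulate_episodes <- function(records, policy = waiting_list_policy()) {
  pid <- unique(records$patient_id)
  if (length(pid) > 1) {
    stop("tabulate_episodes() expects records for a single patient, got: ",
         paste(pid, collapse = ", "))
  }
  n <- nrow(records) %||% 0L
  if (n == 0) {
    return(structure(list(patient_id = if (length(pid)) pid else NA_character_,
                          n_episodes = 0L, assignment = integer(0)),
                     class = "episode_tally"))
  }
  if (any(!is.finite(records$day))) stop("infection days must be finite")
  ord <- order(records$day, seq_len(n), records$itype)
  assignment <- integer(n)
  n_episodes <- 0L
  for (k in seq_len(n)) {
    ci <- ord[k]
    cand <- records[ci, ]
    waiting_days <- -Inf  # day of the most recent record waiting for cand
    waiting_ep <- NA_integer_
    for (j in seq_len(k - 1)) {
      ri <- ord[j]
      r <- records[ri, ]
      window <- if (infection_similar(r, cand, policy)) {
        policy$similar_window
      } else {
        policy$dissimilar_window
      }
      if (cand$day - r$day <= window) {
        if (r$day > waiting_days ||
            (r$day == waiting_days && assignment[ri] < waiting_ep)) {
          waiting_days <- r$day
          waiting_ep <- assignment[ri]
        }
      }
    }
    if (is.na(waiting_ep)) {
      n_episodes <- n_episodes + 1L
      assignment[ci] <- n_episodes
    } else {
      assignment[ci] <- waiting_ep
    }
  }
  structure(list(patient_id = pid, n_episodes = n_episodes,
                 assignment = assignment),
            class = "episode_tally")
}

#' @export
print.episode_tally <- function(x, ...) {
  cat("Episode tally for patient ", x$patient_id, ": ", x$n_episodes,
      " episode(s) from ", length(x$assignment), " record(s)\n", sep = "")
  invisible(x)
}

#' Tabulate episodes for every patient in an infection table
#'
#' @param infections Infection table ([read_infection_table()]).
#' @param patient_ids Optional ids to include even when they have no
#'   records (tallied as 0 episodes).
#' @param policy A [waiting_list_policy()].
#' @return A `data.frame` with columns `patient_id`, `n_episodes`,
#'   `hypersusceptible`, plus an attribute `"tallies"` holding the per
#'   patient `episode_tally` objects (the record-to-episode audit map).
#' @export
tabulate_all_episodes <- function(infections, patient_ids = NULL,
                                  policy = waiting_list_policy()) {
  ids <- union(patient_ids %||% character(0), unique(infections$patient_id))
  tallies <- lapply(ids, function(id) {
    tabulate_episodes(infections[infections$patient_id == id, , drop = FALSE],
                      policy)
  })
  names(tallies) <- ids
  n_ep <- vapply(tallies, `[[`, integer(1), "n_episodes")
  out <- data.frame(patient_id = ids, n_episodes = unname(n_ep),
                    hypersusceptible = unname(n_ep) >= 3L,
                    stringsAsFactors = FALSE)
  attr(out, "tallies") <- tallies
  out
}

#' Classify hypersusceptibility from an episode tally
#'
#' Patients with at least `threshold` independent infection episodes over
#' the whole recovery are labelled hypersusceptible (the case group); the
#' default threshold of 3 episodes matches the case definition of at least
#' three cumulative infection episodes.
#'
#' @param tally An `episode_tally` (or anything with an `n_episodes` field).
#' @param threshold Minimum episode count defining a case (default 3).
#' @return `TRUE` iff `n_episodes >= threshold`.
#' @export
classify_hypersusceptible <- function(tally, threshold = 3L) {
  if (threshold < 1) stop("threshold must be >= 1")
  tally$n_episodes >= threshold
}
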