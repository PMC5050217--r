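test_that("similarity requires all fields equal and no unknowns", {
  a <- make_infections(3)[1, ]
  b <- make_infections(5)[1, ]
  expect_true(infection_similar(a, b))

  c <- make_infections(5, itype = "uti", pathogen = "e. coli")[1, ]
  expect_false(infection_similar(a, c))

  u1 <- make_infections(3, pathogen = "unknown")[1, ]
  u2 <- make_infections(5, pathogen = "unknown")[1, ]
  expect_false(infection_similar(u1, u2))
  # a permissive policy ignoring pathogen would call them similar
  loose <- waiting_list_policy(similarity_fields = c("itype", "mode"))
  expect_true(infection_similar(u1, u2, loose))
})

test_that("episode tabulation follows the waiting-list windows", {
  expect_equal(tabulate_episodes(no_infections())$n_episodes, 0L)

  # similar records: gap 4 <= 6 extends, gap 8 > 6 opens a new episode
  t1 <- tabulate_episodes(make_infections(c(3, 7, 15)))
  expect_equal(t1$n_episodes, 2L)
  expect_equal(t1$assignment, c(1L, 1L, 2L))

  # dissimilar gap 1 <= 2 chains; then similar gap 4 <= 6 from the renewed
  # day-4 anchor keeps everything in one episode
  recs <- rbind(
    make_infections(3),
    make_infections(c(4, 8), itype = "uti", pathogen = "e. coli")
  )
  t2 <- tabulate_episodes(recs)
  expect_equal(t2$n_episodes, 1L)

  # same history without anchor renewal would split: day 8 vs day 3 is
  # dissimilar (gap 5 > 2) and day 8 vs day 4 similar (gap 4 <= 6)
  # so renewal is what merges it; with a tighter similar window it splits
  tight <- waiting_list_policy(similar_window = 3, dissimilar_window = 2)
  expect_equal(tabulate_episodes(recs, tight)$n_episodes, 2L)

  # unknown pathogen forces the short window: gap 4 > 2 splits
  unk <- make_infections(c(3, 7), pathogen = "unknown")
  expect_equal(tabulate_episodes(unk)$n_episodes, 2L)

  expect_error(tabulate_episodes(make_infections(c(1, 2),
                                                 patient_id = c("A", "B"))),
               "single patient")
})

test_that("hypersusceptibility classification uses the >=3 episode rule", {
  tally <- function(k) list(n_episodes = k)
  expect_true(classify_hypersusceptible(tally(3)))
  expect_false(classify_hypersusceptible(tally(2)))
  expect_false(classify_hypersusceptible(tally(0)))
  expect_true(classify_hypersusceptible(tally(2), threshold = 2))
  expect_error(classify_hypersusceptible(tally(3), threshold = 0))
})

test_that("tabulation matches the brute-force oracle on random histories", {
  set.seed(101)
  for (trial in 1:200) {
    recs <- random_infection_records(sample(1:8, 1))
    got <- tabulate_episodes(recs)
    want <- oracle_episodes(recs)
    expect_equal(got$n_episodes, want$n_episodes)
    expect_equal(got$assignment, want$assignment)
  }
})

test_that("tabulation invariants: bounds, permutation and window monotonicity", {
  set.seed(202)
  wide <- waiting_list_policy(similar_window = 9, dissimilar_window = 3)
  for (trial in 1:60) {
    n <- sample(1:8, 1)
    recs <- random_infection_records(n)
    tal <- tabulate_episodes(recs)
    expect_gte(tal$n_episodes, 1L)
    expect_lte(tal$n_episodes, n)
    expect_equal(sort(unique(tal$assignment)), seq_len(tal$n_episodes))

    # shuffling rows never changes the episode count
    perm <- sample(n)
    expect_equal(tabulate_episodes(recs[perm, , drop = FALSE])$n_episodes,
                 tal$n_episodes)

    # enlarging both windows never increases the count
    expect_lte(tabulate_episodes(recs, wide)$n_episodes, tal$n_episodes)
  }

  # all gaps beyond the similar window: every record is its own episode
  far <- make_infections(c(0, 7, 14.5, 22))
  expect_equal(tabulate_episodes(far)$n_episodes, 4L)
})

test_that("per-cohort tabulation covers patients without records", {
  inf <- rbind(make_infections(c(2, 20), patient_id = "A"),
               make_infections(5, patient_id = "B"))
  tal <- tabulate_all_episodes(inf, patient_ids = c("A", "B", "C"))
  expect_setequal(tal$patient_id, c("A", "B", "C"))
  expect_equal(tal$n_episodes[tal$patient_id == "A"], 2L)
  expect_equal(tal$n_episodes[tal$patient_id == "C"], 0L)
  expect_false(any(tal$hypersusceptible))
})
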