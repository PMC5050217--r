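test_that("patient table parses, normalizes aliases and round-trips", {
  csv <- tempfile(fileext = ".csv")
  p <- rbind(
    make_patient("A", sex = "M", etiology = "Flame"),
    make_patient("B", sex = "female", age = 55, tbsa = 60),
    make_patient("C", sex = "Man", inhalation = TRUE)
  )
  utils::write.csv(p, csv, row.names = FALSE)
  got <- read_patient_table(csv)
  expect_equal(nrow(got), 3)
  expect_equal(got$sex, c("male", "female", "male"))
  expect_equal(got$etiology[1], "flame")

  # round trip is field-identical
  csv2 <- tempfile(fileext = ".csv")
  write_patient_table(got, csv2)
  expect_equal(read_patient_table(csv2), got)
})

test_that("patient table validation rejects bad input", {
  csv <- tempfile(fileext = ".csv")
  p <- make_patient("A", tbsa = 150)
  utils::write.csv(p, csv, row.names = FALSE)
  expect_error(read_patient_table(csv), "tbsa")

  utils::write.csv(rbind(make_patient("A"), make_patient("A")), csv,
                   row.names = FALSE)
  expect_error(read_patient_table(csv), "duplicate")

  p <- make_patient("A")
  utils::write.csv(p[, setdiff(names(p), "apacheii")], csv,
                   row.names = FALSE)
  expect_error(read_patient_table(csv), "apacheii")

  p <- make_patient("A"); p$age <- "forty"
  utils::write.csv(p, csv, row.names = FALSE)
  expect_error(read_patient_table(csv), "malformed numeric")
})

test_that("infection table parses and normalizes missing pathogens", {
  csv <- tempfile(fileext = ".csv")
  inf <- make_infections(c(3, 8), pathogen = c("S. aureus", ""))
  utils::write.csv(inf, csv, row.names = FALSE)
  got <- read_infection_table(csv)
  expect_equal(got$pathogen, c("s. aureus", "unknown"))
  expect_error({
    bad <- make_infections(-1)
    utils::write.csv(bad, csv, row.names = FALSE)
    read_infection_table(csv)
  }, "day")
})

test_that("eligibility enumerates one reason per violated criterion", {
  pats <- rbind(
    make_patient("young", age = 15),
    make_patient("electric", etiology = "electrical"),
    make_patient("late_draw", blood_draw_h = 60),
    make_patient("early_inf"),
    make_patient("no_icu", icu_days = 0),
    make_patient("clean")
  )
  inf <- make_infections(0.5, patient_id = "early_inf")  # 12 h < 20 + 24 h
  rep <- apply_eligibility(pats, inf)
  expect_equal(rep$eligible, "clean")
  expect_equal(rep$exclusions$young, "age<16")
  expect_equal(rep$exclusions$electric, "electrical_burn")
  expect_equal(rep$exclusions$late_draw, "draw>48h")
  expect_equal(rep$exclusions$early_inf, "infection_before_draw+24h")
  expect_equal(rep$exclusions$no_icu, "icu<1d")
})

test_that("eligibility boundaries: age 16 in, infection at exactly draw+24h in", {
  pats <- rbind(
    make_patient("a16", age = 16),
    make_patient("b", blood_draw_h = 24)
  )
  inf <- make_infections(2, patient_id = "b")  # 48 h = 24 + 24 exactly
  rep <- apply_eligibility(pats, inf)
  expect_setequal(rep$eligible, c("a16", "b"))
})

test_that("eligibility partitions patients and is monotone in thresholds", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(3:10, 1)
    pats <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_patient(paste0("P", i), age = runif(1, 10, 80),
                   blood_draw_h = runif(1, 1, 70),
                   icu_days = sample(0:5, 1),
                   etiology = sample(c("flame", "electrical"), 1))
    }))
    inf <- make_infections(runif(1, 0, 4), patient_id = "P1")
    rep <- apply_eligibility(pats, inf)
    expect_equal(length(rep$eligible) + length(rep$exclusions), n)
    expect_length(intersect(rep$eligible, names(rep$exclusions)), 0)
    # relaxing the draw window never shrinks the eligible set
    rep2 <- apply_eligibility(pats, inf, max_draw_h = 72)
    expect_true(all(rep$eligible %in% rep2$eligible))
  }
})

test_that("empty patient list yields an empty report", {
  rep <- apply_eligibility(make_patient()[0, ], no_infections())
  expect_length(rep$eligible, 0)
  expect_length(rep$exclusions, 0)
})

test_that("eligibility report serializes to JSON", {
  pats <- rbind(make_patient("a", age = 10), make_patient("b"))
  rep <- apply_eligibility(pats, no_infections())
  path <- tempfile(fileext = ".json")
  write_eligibility_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$eligible, "b")
  expect_equal(back$exclusions$a[[1]], "age<16")
})
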