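test_that("recoding maps raw fields to the analysis categories", {
  cohort <- raw_cohort(list(
    raw_record(maternal_age_years = 19L, gestational_weeks_at_registration = 12L,
               feeling_at_pregnancy = "no_feeling"),
    raw_record(maternal_age_years = 24L, gestational_weeks_at_registration = 11L,
               feeling_at_pregnancy = "unexpected_puzzled"),
    raw_record(maternal_age_years = 39L,
               gestational_weeks_at_registration = NA_integer_,
               feeling_at_pregnancy = "other"),
    raw_record(maternal_age_years = 40L, smoking = NA_character_)
  ))
  rec <- recode_cohort(cohort)
  expect_equal(as.character(rec$maternal_age), c("<20", "20-24", "25-39", ">=40"))
  # 12 weeks is the inclusive boundary of "late"
  expect_equal(as.character(rec$late_registration), c("yes", "no", "not_answered", "no"))
  expect_equal(as.character(rec$feeling_at_pregnancy)[1:3],
               rep("unexpected_other", 3))
  expect_equal(as.character(rec$smoking), c("no", "no", "no", "not_answered"))
})

test_that("blank cells become not_investigated only where the municipality skipped the item", {
  cohort <- raw_cohort(list(
    raw_record(municipality_id = "m1", marital_status = NA_character_),
    raw_record(municipality_id = "m2", marital_status = NA_character_)
  ))
  rec <- recode_cohort(cohort, availability = list(m1 = "marital_status"))
  expect_equal(as.character(rec$marital_status),
               c("not_investigated", "not_answered"))
})

test_that("recoding rejects invalid records", {
  expect_error(recode_cohort(raw_cohort(list(raw_record(maternal_age_years = -1L)))),
               "maternal_age_years")
  expect_error(recode_cohort(raw_cohort(list(raw_record(maternal_age_years = 61L)))),
               "maternal_age_years")
  expect_error(recode_cohort(raw_cohort(list(raw_record(smoking = "sometimes")))),
               "unknown label")
  expect_error(recode_cohort(raw_cohort(list(raw_record(outcome_rccrc = NA)))),
               "outcome")
  expect_error(recode_cohort(raw_cohort(list(raw_record()))[0, ]), "empty")
})

test_that("recoding is deterministic", {
  cohort <- raw_cohort(lapply(1:8, function(i) {
    raw_record(household_id = paste0("h", i),
               maternal_age_years = sample(16:45, 1))
  }))
  expect_identical(recode_cohort(cohort), recode_cohort(cohort))
  one <- recode_record(raw_record(maternal_age_years = 19L))
  expect_identical(one$maternal_age, "<20")
  expect_identical(one, recode_record(raw_record(maternal_age_years = 19L)))
})

test_that("the not_answered merge rule pools only small groups into the reference", {
  tb <- prenatalrisk:::new_count_table(
    "abortion_history", c("no", "yes", "not_answered"),
    c(TRUE, FALSE, FALSE), c(831, 59, 3), c(7, 4, 0)
  )
  merged <- merge_small_not_answered(tb)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$category[merged$reference], "no/not_answered")
  expect_equal(merged$n_total[merged$reference], 834)
  expect_equal(sum(merged$n_total), sum(tb$n_total))
  expect_equal(sum(merged$n_events), sum(tb$n_events))

  big_na <- prenatalrisk:::new_count_table(
    "feeling_at_pregnancy", c("happy", "not_answered"),
    c(TRUE, FALSE), c(886, 7), c(10, 1)
  )
  expect_identical(merge_small_not_answered(big_na), big_na)

  ni_only <- prenatalrisk:::new_count_table(
    "passive_smoking", c("no", "not_investigated"),
    c(TRUE, FALSE), c(500, 3), c(9, 2)
  )
  # not_investigated is never merged, however small
  expect_identical(merge_small_not_answered(ni_only), ni_only)
})

test_that("count tables agree with a hand tally and conserve totals", {
  cohort <- raw_cohort(lapply(1:10, function(i) {
    raw_record(household_id = paste0("h", i),
               smoking = c("yes", "no", "no", "stopped_after_confirmation",
                           "no", "yes", "no", "no", "stopped_after_confirmation",
                           "no")[i],
               outcome_rccrc = i <= 3)
  }))
  tb <- build_count_table(recode_cohort(cohort), "smoking")
  expect_equal(tb$category, c("no", "stopped_after_confirmation", "yes"))
  expect_equal(tb$n_total, c(6L, 2L, 2L))
  expect_equal(tb$n_events, c(2L, 0L, 1L))
  expect_equal(sum(tb$n_total), 10)
  expect_equal(sum(tb$n_events), 3)

  single <- build_count_table(
    recode_cohort(raw_cohort(list(raw_record()))), "alcohol")
  expect_equal(nrow(single), 1)
  expect_equal(single$n_events, 0L)
})

test_that("tabulate-then-merge equals merge-then-tabulate", {
  set.seed(11)
  cohort <- raw_cohort(lapply(1:60, function(i) {
    raw_record(household_id = paste0("h", i),
               abortion_history = sample(c("no", "yes", NA), 1,
                                         prob = c(0.8, 0.15, 0.05)),
               worries_anxiety = sample(c("no", "yes", NA), 1,
                                        prob = c(0.5, 0.3, 0.2)),
               outcome_rccrc = runif(1) < 0.1)
  }))
  rec <- recode_cohort(cohort)
  for (v in c("abortion_history", "worries_anxiety")) {
    a <- merge_small_not_answered(build_count_table(rec, v))
    b <- build_count_table(collapse_small_not_answered(rec), v)
    expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  }
})

test_that("the packaged published-cohort fixture is internally consistent", {
  fx <- load_table1_fixture()
  expect_length(fx, 17)
  for (tb in fx) {
    expect_equal(sum(tb$n_total), 893)
    expect_equal(sum(tb$n_events), 11)
    expect_true(all(tb$n_events <= tb$n_total))
    expect_equal(sum(tb$reference), 1)
  }
  expect_equal(fx$smoking$n_total, c(776L, 94L, 23L))
  expect_equal(fx$smoking$n_events, c(6L, 3L, 2L))
  expect_equal(fx$marital_status$n_total, c(423L, 27L, 26L, 417L))
  expect_equal(fx$marital_status$n_events, c(2L, 2L, 1L, 6L))
})

test_that("a corrupted fixture is rejected", {
  fx_path <- system.file("extdata", "table1_counts.csv", package = "prenatalrisk")
  raw <- readr::read_csv(fx_path, show_col_types = FALSE)
  raw$n_total[1] <- raw$n_total[1] + 1L
  bad <- tempfile(fileext = ".csv")
  readr::write_csv(raw, bad)
  expect_error(load_table1_fixture(bad), "integrity")
})
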