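test_that("same-day classification compares entry and appointment dates exactly", {
  recs <- make_records(c("a", "b", "c"),
                       appointment_date = c("2016-11-01", "2016-11-01", "2016-11-02"),
                       entry_date = c("2016-11-01", "2016-11-02", "2016-11-01"))
  expect_identical(classify_same_day(recs), c(TRUE, FALSE, FALSE))
})

test_that("completeness requires fields, a real visit reason, and referral details for initials", {
  base <- make_records("a", appointment_date = "2016-11-01")
  expect_true(classify_complete(base))
  expect_false(classify_complete(make_records("b", appointment_date = "2016-11-01",
                                              visit_reason = "other")))
  # initial encounters additionally need source and a known referral date
  expect_false(classify_complete(make_records("c", encounter_type = "initial",
                                              appointment_date = "2016-11-01",
                                              referral_date = "2016-10-01")))
  expect_false(classify_complete(make_records("d", encounter_type = "initial",
                                              appointment_date = "2016-11-01",
                                              referral_date = "1900-01-01",
                                              referral_source = "family_physician")))
  expect_true(classify_complete(make_records("e", encounter_type = "initial",
                                             appointment_date = "2016-11-01",
                                             referral_date = "2016-10-01",
                                             referral_source = "family_physician")))
  # a missing required field fails; follow-ups don't need referral details
  missing_reason <- make_records("f", appointment_date = "2016-11-01")
  missing_reason$visit_reason <- ""
  expect_false(classify_complete(missing_reason))
})

test_that("an unknown name in required_fields is a configuration error", {
  recs <- make_records("a", appointment_date = "2016-11-01")
  expect_error(classify_complete(recs, c("user_id", "badger")),
               "badger", class = "dqspc_config_error")
})

test_that("validity applies the four date rules with calendar-month arithmetic", {
  # non-strict appointment <= entry; strict > 2008-01-01; strict < 4 months
  expect_true(classify_valid(make_records("a", appointment_date = "2016-11-01")))
  expect_false(classify_valid(make_records("b", appointment_date = "2016-11-02",
                                           entry_date = "2016-11-01")))
  expect_false(classify_valid(make_records("c", appointment_date = "2007-06-01",
                                           entry_date = "2016-11-01")))
  expect_false(classify_valid(make_records("d", appointment_date = "2016-06-01",
                                           entry_date = "2016-11-01")))
  # 6-month referral gap, non-strict, skipped for the sentinel
  expect_true(classify_valid(make_records("e", encounter_type = "initial",
                                          appointment_date = "2016-07-15",
                                          referral_date = "2016-01-15",
                                          referral_source = "s")))
  expect_false(classify_valid(make_records("f", encounter_type = "initial",
                                           appointment_date = "2016-07-16",
                                           referral_date = "2016-01-15",
                                           referral_source = "s")))
  expect_true(classify_valid(make_records("g", encounter_type = "initial",
                                          appointment_date = "2016-07-16",
                                          referral_date = "1900-01-01",
                                          referral_source = "s")))
})

test_that("the committed clause fixture reproduces the hand-derived flag table exactly", {
  recs <- read_encounters(test_path("fixtures", "quality-clauses.csv"))
  expected <- readr::read_csv(test_path("fixtures", "quality-clauses-expected.csv"),
                              show_col_types = FALSE)
  flags <- score_dataset(recs)
  expect_identical(flags$record_id, expected$record_id)
  expect_identical(flags$same_day, expected$same_day)
  expect_identical(flags$complete, expected$complete)
  expect_identical(flags$valid, expected$valid)
})

test_that("score_dataset yields one flag row per record, order preserved, and is permutation-pure", {
  d <- generate_cohort(small_config(seed = 21L))
  flags <- score_dataset(d)
  expect_identical(nrow(flags), nrow(d))
  expect_identical(flags$record_id, d$record_id)
  perm <- withr::with_seed(1, sample(nrow(d)))
  flags_perm <- score_dataset(d[perm, ])
  expect_identical(flags_perm$same_day, flags$same_day[perm])
  expect_identical(flags_perm$complete, flags$complete[perm])
  expect_identical(flags_perm$valid, flags$valid[perm])
})

test_that("same-day entry implies the entry-side validity subconditions", {
  d <- generate_cohort(small_config(seed = 31L, p_validity_error = 0.2))
  flags <- score_dataset(d)
  sd_idx <- flags$same_day
  expect_true(all(d$appointment_date[sd_idx] <= d$entry_date[sd_idx]))
  expect_true(all(d$entry_date[sd_idx] - d$appointment_date[sd_idx] == 0))
})

test_that("aggregation computes percentages per group and omits empty groups", {
  recs <- make_records(paste0("r", 1:4), user_id = "u9",
                       appointment_date = "2016-10-05",
                       entry_date = c("2016-10-05", "2016-10-05", "2016-10-05",
                                      "2016-10-06"))
  flags <- score_dataset(recs)
  by_user <- aggregate_measures(flags, recs, "by_user")
  expect_identical(nrow(by_user), 1L)
  expect_identical(by_user$n_records, 4L)
  expect_equal(by_user$pct_same_day, 75.0)
  expect_equal(by_user$pct_complete, 100.0)

  recs2 <- make_records(paste0("m", 1:3),
                        appointment_date = c("2016-10-03", "2016-11-04", "2016-11-07"))
  by_month <- aggregate_measures(score_dataset(recs2), recs2, "by_month")
  expect_identical(by_month$month, c("2016-10", "2016-11"))
  expect_identical(by_month$n_records, c(1L, 2L))
})

test_that("the clause fixture aggregates by month to a hand-computed series", {
  recs <- read_encounters(test_path("fixtures", "quality-clauses.csv"))
  series <- aggregate_measures(score_dataset(recs), recs, "by_month")
  expect_identical(series$month, c("2008-01", "2016-06", "2016-07", "2016-11"))
  expect_identical(series$n_records, c(1L, 2L, 2L, 7L))
  expect_equal(series$pct_same_day, c(100, 0, 100, 100 * 5 / 7))
  expect_equal(series$pct_complete, c(100, 100, 100, 100 * 4 / 7))
  expect_equal(series$pct_valid, c(0, 50, 50, 100 * 6 / 7))
})

test_that("conservation: flagged plus unflagged records equal the group size", {
  d <- generate_cohort(small_config(seed = 41L))
  flags <- score_dataset(d)
  series <- aggregate_measures(flags, d, "by_user")
  for (m in c("pct_same_day", "pct_complete", "pct_valid")) {
    counts <- series[[m]] / 100 * series$n_records
    expect_equal(counts, round(counts))
    expect_true(all(series[[m]] >= 0 & series[[m]] <= 100))
  }
})

test_that("window grouping needs an intervention date and assigns 8-week windows by appointment", {
  d <- generate_cohort(small_config(seed = 51L))
  flags <- score_dataset(d)
  expect_error(aggregate_measures(flags, d, "by_user_and_window"),
               class = "dqspc_config_error")
  series <- aggregate_measures(flags, d, "by_user_and_window",
                               intervention_date = as.Date("2016-11-28"))
  expect_true(all(series$window %in% c("pre", "post")))
  # window boundaries: day before the intervention is pre; day 56 is outside
  edge <- make_records(c("w1", "w2", "w3", "w4"),
                       appointment_date = c("2016-11-27", "2016-11-28",
                                            "2016-10-03", "2016-10-02"))
  es <- aggregate_measures(score_dataset(edge), edge, "by_user_and_window",
                           intervention_date = as.Date("2016-11-28"))
  expect_identical(sum(es$n_records), 3L)
})

test_that("an error-free, always-same-day cohort scores 100 on every measure in every month", {
  cfg <- small_config(seed = 61L,
                      p_same_day_pre = 1, p_same_day_post = 1,
                      p_validity_error = 0,
                      p_reason_other_pre = 0, p_reason_other_post = 0,
                      p_referral_unknown_pre = 0, p_referral_unknown_spike = 0,
                      quarter_end_delay_boost = 1)
  d <- generate_cohort(cfg)
  series <- aggregate_measures(score_dataset(d), d, "by_month")
  expect_true(all(series$pct_same_day == 100))
  expect_true(all(series$pct_complete == 100))
  expect_true(all(series$pct_valid == 100))
})
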