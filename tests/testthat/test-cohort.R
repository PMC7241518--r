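# Eligibility algorithm: index dates, enrollment, encounter quarters, and
# the operationalized 36-month outcome.

test_that("calendar month arithmetic clamps month ends and passes NA through", {
  expect_equal(add_months(as.Date("2010-01-31"), 1), as.Date("2010-02-28"))
  expect_equal(add_months(as.Date("2012-01-31"), 1), as.Date("2012-02-29"))
  expect_equal(add_months(as.Date("2010-06-01"), -6), as.Date("2009-12-01"))
  # a leading NA (e.g. a patient with no index date) must not derail the rest
  expect_equal(add_months(as.Date(c(NA, "2010-01-31")), 1),
               as.Date(c(NA, "2010-02-28")))
  expect_equal(quarter_id(as.Date(c("2010-03-31", "2010-04-01", NA))),
               c("2010Q1", "2010Q2", NA))
})

test_that("index date is the first ER/LA fill whose 90-day window reaches 60 days' supply", {
  # two 30-day fills six weeks apart qualify from the first fill
  d <- make_dispensings(c("2010-01-01", "2010-02-15"), c(30, 30))
  expect_equal(find_index_date(d), as.Date("2010-01-01"))
  # a single 30-day fill can never reach 60
  expect_true(is.na(find_index_date(make_dispensings("2010-01-01", 30))))
  # one 90-day fill qualifies on its own
  expect_equal(find_index_date(make_dispensings("2012-05-05", 90)),
               as.Date("2012-05-05"))
  # fills 91 days apart never share a window
  d <- make_dispensings(c("2010-01-01", "2010-04-02"), c(30, 30))
  expect_true(is.na(find_index_date(d)))
  # IR and OUD-treatment fills do not count toward qualification
  d <- rbind(make_dispensings("2010-01-01", 90, class = "IR_opioid"),
             make_dispensings("2010-01-05", 90, class = "OUD_treatment"))
  expect_true(is.na(find_index_date(d)))
  expect_error(find_index_date(make_dispensings("2010-01-01", -5)),
               "negative days_supply")
})

test_that("fill-anchored index search agrees with the daily-grid oracle", {
  set.seed(404)
  for (rep in 1:200) {
    d <- random_fill_set()
    expect_identical(find_index_date(d), oracle_index_date(d),
                     label = paste("replicate", rep))
  }
})

test_that("adding an ER/LA fill never delays or destroys an index date", {
  set.seed(405)
  for (rep in 1:50) {
    d <- random_fill_set()
    idx <- find_index_date(d)
    extra <- make_dispensings(as.Date("2010-01-01") + sample(0:400, 1),
                              sample(c(28, 30, 90), 1))
    idx2 <- find_index_date(rbind(d, extra))
    if (!is.na(idx)) {
      expect_false(is.na(idx2))
      expect_lte(as.numeric(idx2), as.numeric(idx))
    }
  }
})

test_that("continuous enrollment requires 6 months pre and 18 months post index", {
  cfg <- eligibility_config()
  ample <- make_spans("2009-01-01", "2012-12-31")
  expect_true(check_continuous_enrollment(ample, as.Date("2010-06-01"), cfg))
  # only 3 months before the index
  late <- make_spans("2010-03-01", "2012-12-31")
  expect_false(check_continuous_enrollment(late, as.Date("2010-06-01"), cfg))
  # gap bridging honours the tolerance
  split2 <- make_spans(c("2009-01-01", "2010-09-11"),
                       c("2010-08-31", "2012-12-31"))
  expect_false(check_continuous_enrollment(split2, as.Date("2010-06-01"), cfg))
  tol30 <- eligibility_config(gap_tolerance = 30)
  expect_true(check_continuous_enrollment(split2, as.Date("2010-06-01"), tol30))
})

test_that("encounter quarters count distinct calendar quarters", {
  enc <- data.frame(date = as.Date(c("2010-02-01", "2010-05-01", "2010-08-01",
                                     "2010-11-01", "2011-02-01", "2011-05-01",
                                     "2011-08-01", "2011-11-01")))
  expect_equal(count_encounter_quarters(enc), 8)
  crowded <- data.frame(date = as.Date("2010-01-15") + 0:19)
  expect_equal(count_encounter_quarters(crowded), 1)
  expect_equal(count_encounter_quarters(data.frame(date = as.Date(character(0)))), 0)
})

cohort_fixture <- function(onset = NA, problem_use = !is.na(onset)) {
  enc_dates <- seq(as.Date("2009-02-01"), by = "3 months", length.out = 10)
  make_population(
    demographics = make_demographics(),
    enrollment = make_spans("2008-01-01", "2013-12-31"),
    dispensings = make_dispensings(c("2010-01-01", "2010-02-15"), c(30, 30)),
    encounters = data.frame(patient_id = "P000001", date = enc_dates,
                            setting = "outpatient", stringsAsFactors = FALSE),
    labels = data.frame(patient_id = "P000001", problem_use = problem_use,
                        onset_date = as.Date(onset), stringsAsFactors = FALSE))
}

test_that("outcome is positive for onsets before or during the window, negative after", {
  # index 2010-01-01 -> 36-month window 2009-01-01 .. 2011-12-31
  early <- build_cohort(cohort_fixture(onset = "2008-10-01"))
  expect_equal(nrow(early), 1)
  expect_equal(early$observation_start, as.Date("2009-01-01"))
  expect_equal(early$observation_end, as.Date("2011-12-31"))
  expect_true(early$outcome_36m)   # onset 3 months before the window
  inside <- build_cohort(cohort_fixture(onset = "2011-06-01"))
  expect_true(inside$outcome_36m)
  after <- build_cohort(cohort_fixture(onset = "2012-01-01"))
  expect_false(after$outcome_36m)  # one day past the window end
  none <- build_cohort(cohort_fixture())
  expect_false(none$outcome_36m)
})

test_that("eligible patients without a reference label are a data error", {
  pop <- cohort_fixture(onset = "2011-06-01")
  pop$labels <- pop$labels[0, ]
  expect_error(build_cohort(pop), "P000001")
})

test_that("cohort membership is invariant to record order", {
  pop <- generate_population(sim_config(n_patients = 50, seed = 77))
  ref <- build_cohort(pop)
  set.seed(1)
  for (tbl in c("dispensings", "encounters", "enrollment"))
    pop[[tbl]] <- pop[[tbl]][sample(nrow(pop[[tbl]])), ]
  shuffled <- build_cohort(pop)
  expect_equal(shuffled[order(shuffled$patient_id), ],
               ref[order(ref$patient_id), ], ignore_attr = TRUE)
})

test_that("ineligible patients fail with informative flags in audit mode", {
  pop <- cohort_fixture(onset = "2011-06-01")
  pop$demographics$excluded <- TRUE
  audit <- build_cohort(pop, keep_all = TRUE)
  expect_false(audit$eligible)
  expect_false(audit$eligible_not_excluded)
  expect_true(audit$eligible_index)
  expect_equal(nrow(build_cohort(pop)), 0)
})
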