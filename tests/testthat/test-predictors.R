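# Predictor engine: MEQ series, overlap detection, builder families, the
# matrix, and the risk-ratio screen.

test_that("daily MEQ follows dose arithmetic and adds across overlapping fills", {
  win <- as.Date(c("2010-01-01", "2010-03-31"))
  # 30 units x 10 mg x factor 1.5 over 30 days -> 15 MEQ/day
  one <- make_dispensings("2010-01-01", 30, quantity = 30, mg = 10, meq = 1.5)
  s <- daily_meq_series(one, win)
  expect_equal(s[1:30], rep(15, 30), ignore_attr = TRUE)
  expect_equal(s[31:90], rep(0, 60), ignore_attr = TRUE)
  # identical overlapping fills double the dose on overlap days
  two <- rbind(one, one)
  expect_equal(daily_meq_series(two, win)[1:30], rep(30, 30),
               ignore_attr = TRUE)
  # no opioid fills -> all-zero series
  bzd <- make_dispensings("2010-01-10", 30, class = "benzodiazepine")
  expect_equal(sum(daily_meq_series(bzd, win)), 0)
  expect_error(daily_meq_series(make_dispensings("2010-01-01", 0), win),
               "days_supply")
})

test_that("the MEQ series conserves total dispensed morphine equivalents", {
  set.seed(11)
  for (rep in 1:25) {
    d <- random_fill_set()
    if (nrow(d) == 0) next
    win <- c(min(d$dispense_date) - 10, max(d$dispense_date) + 120)
    expect_equal(sum(daily_meq_series(d, win)),
                 sum(d$quantity * d$mg_per_unit * d$meq_factor))
  }
})

test_that("the canonical weekend overlap chain is detected", {
  # Sat Jan 2, Mon Jan 4, Sun Jan 10 2010; coverage intervals all chain
  fills <- make_dispensings(c("2010-01-02", "2010-01-04", "2010-01-10"),
                            c(10, 7, 14), class = "IR_opioid")
  expect_true(detect_overlap_events(fills))
  # the same middle fill moved to Wednesday fails the day-of-week filter
  wed <- make_dispensings(c("2010-01-02", "2010-01-06", "2010-01-10"),
                          c(10, 7, 14), class = "IR_opioid")
  expect_false(detect_overlap_events(wed))
  # punctual monthly refills never overlap
  monthly <- make_dispensings(as.Date("2010-01-01") + c(0, 30, 60, 90),
                              rep(30, 4), class = "IR_opioid")
  expect_false(detect_overlap_events(monthly, max_days_supply = 30,
                                     dow_set = NULL))
  expect_equal(detect_overlap_events(fills, value = "count"), 3L)
})

test_that("overlap detection agrees with the coverage-day brute force", {
  set.seed(406)
  for (rep in 1:200) {
    d <- random_fill_set()
    expect_identical(detect_overlap_events(d),
                     oracle_overlap_flag(d), label = paste("replicate", rep))
  }
})

test_that("package weekday labels match POSIXlt", {
  dates <- as.Date("2009-12-28") + 0:20
  expect_equal(probuse:::weekdays_abbrev(dates), oracle_weekday(dates))
})

predictor_fixture <- function() {
  member <- make_member("2011-01-01")  # window 2010-01-01 .. 2012-12-31
  dx <- data.frame(patient_id = "P000001",
                   date = as.Date(c("2010-02-01", "2010-11-15", "2012-08-01",
                                    "2013-06-01")),
                   code = c("304.01", "304.02", "304.01", "304.01"),
                   setting = "outpatient", stringsAsFactors = FALSE)
  pop <- make_population(demographics = make_demographics(), diagnoses = dx)
  list(member = member, pop = pop)
}

test_that("diagnosis builders bucket by calendar quarter", {
  fx <- predictor_fixture()
  flag <- predictor_spec("oud_ever", "diagnosis_flag",
                         list(codes = c("304.")))
  expect_equal(build_predictor(fx$pop, flag, fx$member), 1)
  # 3 of 12 observation quarters carry a code -> 0.25 (out-of-window code ignored)
  pq <- predictor_spec("oud_pq", "pct_quarters", list(codes = c("304.")))
  expect_equal(build_predictor(fx$pop, pq, fx$member), 0.25)
  cnt <- predictor_spec("oud_n", "diagnosis_count",
                        list(codes = c("304."), grain = "overall"))
  expect_equal(build_predictor(fx$pop, cnt, fx$member), 3)
})

test_that("interaction terms are indicator products", {
  fx <- predictor_fixture()  # born 1960: age 50 at index
  base <- predictor_spec("oud_ever", "diagnosis_flag", list(codes = c("304.")))
  ix <- predictor_spec("young_oud", "interaction",
                       list(age_group = "18-34", base = base))
  expect_equal(build_predictor(fx$pop, ix, fx$member), 0)
  old <- predictor_spec("older_oud", "interaction",
                        list(age_group = "35+", base = base))
  expect_equal(build_predictor(fx$pop, old, fx$member), 1)
})

test_that("the matrix is complete, zero-filled, and order-invariant", {
  specs <- default_predictor_library()
  expect_gte(length(specs), 100)
  # empty cohort: full header, no rows
  pop <- generate_population(sim_config(n_patients = 30, seed = 2))
  coh <- build_cohort(pop)
  empty <- build_matrix(pop, coh[0, ], specs)
  expect_equal(dim(empty), c(0, length(specs)))
  X <- build_matrix(pop, coh, specs)
  expect_false(anyNA(X))
  expect_equal(rownames(X), coh$patient_id)
  binary <- vapply(specs, function(s) s$output == "binary", logical(1))
  expect_true(all(X[, binary] %in% c(0, 1)))
  expect_length(attr(X, "specs"), length(specs))
  # shuffling input record order changes nothing
  set.seed(3)
  pop2 <- pop
  for (tbl in c("dispensings", "diagnoses", "encounters", "procedures"))
    pop2[[tbl]] <- pop2[[tbl]][sample(nrow(pop2[[tbl]])), ]
  expect_equal(build_matrix(pop2, coh, specs), X)
})

test_that("a patient with no events yields zeros plus demographics", {
  pop <- make_population(demographics = make_demographics())
  member <- make_member("2011-01-01")
  X <- build_matrix(pop, member, default_predictor_library())
  nonzero <- colnames(X)[X[1, ] != 0]
  expect_true(all(grepl("^(age|sex)", nonzero)))
  expect_equal(unname(X[1, "sex_female"]), 1)
  expect_equal(unname(X[1, "age_at_index"]), 50)
})

test_that("risk-ratio screening follows the percentage formula", {
  # 200 positives (80 TRUE = 40%), 800 negatives (80 TRUE = 10%) -> RR 4
  x <- c(rep(1, 80), rep(0, 120), rep(1, 80), rep(0, 720))
  y <- c(rep(TRUE, 200), rep(FALSE, 800))
  X <- cbind(pred = x, everyone = 1, pos_only = as.numeric(y))
  res <- risk_ratio_screen(X, y)
  expect_equal(res$rr[res$predictor == "pred"], 4.0)
  expect_equal(res$n_true[res$predictor == "pred"], 160)
  expect_equal(res$rr[res$predictor == "everyone"], 1.0)
  # no negatives carry it: undefined, not infinite
  expect_true(res$undefined[res$predictor == "pos_only"])
  expect_true(is.na(res$rr[res$predictor == "pos_only"]))
  # continuous predictors respect configured cut-points
  Xc <- cbind(cont = c(rep(5, 200), rep(1, 800)))
  r2 <- risk_ratio_screen(Xc, y, dichotomization_rules = list(cont = 3))
  expect_true(r2$undefined)
  expect_equal(r2$n_true, 200)
})

test_that("predictors targeting elevated streams screen with RR > 1", {
  pop <- generate_population(sim_config(n_patients = 400, seed = 55))
  coh <- build_cohort(pop)
  X <- build_matrix(pop, coh)
  res <- risk_ratio_screen(X, coh$outcome_36m)
  for (nm in c("dx_opioid_dependence_ever", "oud_treatment_ever",
               "concomitant_ever", "er_visits"))
    expect_gt(res$rr[res$predictor == nm], 1)
})
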