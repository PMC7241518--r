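# Evaluation: confusion metrics, ROC, cut-point schemes, the ICD-9
# comparator, binomial CIs, and the combined report.

test_that("confusion metrics follow the four quoted formulas", {
  # TP=90 FN=10 FP=60 TN=840
  scores <- c(rep(1, 90), rep(0, 10), rep(1, 60), rep(0, 840))
  outcomes <- c(rep(TRUE, 100), rep(FALSE, 900))
  m <- confusion_metrics(scores, outcomes, 1)
  expect_equal(m$sensitivity, 0.900)
  expect_equal(m$specificity, 840 / 900)
  expect_equal(m$ppv, 0.600)
  expect_equal(m$npv, 840 / 850)
  expect_equal(m$predicted_prevalence, 0.15)
  # identities on integer counts
  expect_equal(m$ppv * (m$tp + m$fp), m$tp)
  expect_equal(m$sensitivity + m$fn / (m$tp + m$fn), 1)
})

test_that("degenerate cuts classify everyone one way", {
  scores <- c(0.2, 0.5, 0.9)
  outcomes <- c(FALSE, TRUE, TRUE)
  lo <- confusion_metrics(scores, outcomes, 0)
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  expect_equal(lo$predicted_prevalence, 1)
  hi <- confusion_metrics(scores, outcomes, 2)
  expect_true(is.na(hi$ppv))          # undefined, not 0
  expect_equal(hi$npv, 1 / 3)
})

test_that("ROC points are monotone with the right endpoints", {
  set.seed(41)
  scores <- runif(200)
  outcomes <- rbinom(200, 1, plogis(4 * scores - 2)) == 1
  r <- roc_points(scores, outcomes)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  # perfect separation passes through (0, 1)
  rp <- roc_points(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(any(rp$fpr == 0 & rp$tpr == 1))
  # sign reversal reflects the curve: AUC flips around 1/2
  expect_equal(roc_auc(-scores, outcomes), 1 - roc_auc(scores, outcomes),
               tolerance = 1e-9)
  expect_error(roc_points(scores, rep(TRUE, 200)), "one positive and one")
})

test_that("uninformative scores give AUC about one half", {
  set.seed(42)
  scores <- runif(4000)
  outcomes <- rbinom(4000, 1, 0.3) == 1
  expect_equal(roc_auc(scores, outcomes), 0.5, tolerance = 0.05)
})

test_that("cut-point selection matches exhaustive enumeration", {
  set.seed(43)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)
    outcomes <- rbinom(n, 1, 0.4) == 1
    if (!any(outcomes) || all(outcomes)) next
    for (scheme in c("sensitivity", "specificity", "ppv")) {
      target <- sample(c(0.75, 0.8, 0.9), 1)
      expected <- oracle_cutpoint(scores, outcomes, scheme, target)
      if (is.null(expected)) {
        expect_error(select_cutpoint(scores, outcomes, scheme, target),
                     "unattainable")
      } else {
        expect_equal(select_cutpoint(scores, outcomes, scheme, target),
                     expected)
      }
    }
    expect_equal(select_cutpoint(scores, outcomes, "balanced"),
                 oracle_cutpoint(scores, outcomes, "balanced"))
  }
})

test_that("hand-built cut-point cases behave as specified", {
  # 4 positives of 10; target sensitivity 0.75 keeps >= 3 true positives
  scores <- c(0.9, 0.8, 0.6, 0.3, 0.7, 0.5, 0.4, 0.2, 0.15, 0.1)
  outcomes <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6))
  cut <- select_cutpoint(scores, outcomes, "sensitivity", 0.75)
  m <- confusion_metrics(scores, outcomes, cut)
  expect_gte(m$sensitivity, 0.75)
  expect_gte(m$tp, 3)
  # target sensitivity 1.0 must classify the weakest positive correctly
  cut1 <- select_cutpoint(scores, outcomes, "sensitivity", 1.0)
  expect_lte(cut1, min(scores[outcomes]))
  # a balanced point where sensitivity equals PPV exactly
  sc <- c(0.9, 0.8, 0.2, 0.1)
  oc <- c(TRUE, FALSE, TRUE, FALSE)
  cutb <- select_cutpoint(sc, oc, "balanced")
  mb <- confusion_metrics(sc, oc, cutb)
  expect_equal(mb$sensitivity, mb$ppv)
})

test_that("the ICD-9 comparator respects the observation window and heroin exclusion", {
  cohort <- make_member("2011-01-01")  # window 2010-01-01 .. 2012-12-31
  dx <- function(code, date) data.frame(
    patient_id = "P000001", date = as.Date(date), code = code,
    setting = "outpatient", stringsAsFactors = FALSE)
  expect_true(icd9_classifier(dx("304.01", "2011-05-01"), cohort))
  expect_false(icd9_classifier(dx("304.01", "2013-01-01"), cohort))
  expect_false(icd9_classifier(dx("965.01", "2011-05-01"), cohort))
  expect_true(icd9_classifier(dx("965.00", "2011-05-01"), cohort))
  expect_false(icd9_classifier(dx("305.1", "2011-05-01"), cohort))
})

test_that("binomial intervals reproduce the power-statement arithmetic", {
  expect_equal(binomial_ci(0.80, 480, 0.95), c(76, 84))
  expect_equal(binomial_ci(1.0, 10), c(100, 100))
  expect_equal(binomial_ci(0.5, 100, 0.95), c(40, 60))
  exact <- binomial_ci(0.8, 480, method = "exact")
  expect_true(exact[1] >= 70 && exact[2] <= 90)
})

test_that("the report selects cuts on training data and carries them to validation", {
  set.seed(44)
  n <- 600
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * x - 0.5)) == 1
  scores <- plogis(2.5 * x - 0.5)
  tr <- seq_len(n) <= 400
  rep3 <- cutpoint_report(scores[tr], y[tr], scores[!tr], y[!tr],
                        comparator = list(train = x[tr] > 1.5,
                                          validation = x[!tr] > 1.5))
  expect_equal(nrow(rep3), 11)
  expect_setequal(unique(rep3$scheme),
                  c("sensitivity", "specificity", "ppv", "balanced",
                    "icd9_comparator"))
  tgt <- rep3[rep3$scheme != "balanced" & rep3$scheme != "icd9_comparator", ]
  for (k in seq_len(nrow(tgt)))
    expect_gte(tgt[[paste0(tgt$scheme[k], "_train")]][k], tgt$target[k])
  # validation metrics are computed at the training cut, not re-optimized
  row1 <- rep3[1, ]
  mv <- confusion_metrics(scores[!tr], y[!tr], row1$cut)
  expect_equal(row1$sensitivity_valid, mv$sensitivity)
  expect_error(cutpoint_report(numeric(0), logical(0), scores, y), "empty")
})
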