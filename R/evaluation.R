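#' Confusion-matrix metrics at a risk-score cut point
#'
#' Patients with `score >= cut` classify positive, all others negative.
#' Metrics follow the standard definitions: sensitivity `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`; predicted
#' prevalence is the classified-positive fraction `(TP+FP)/n`. Ratios with
#' empty denominators are reported as `NA`, never coerced to 0 or 1.
#'
#' @param scores numeric risk scores.
#' @param outcomes logical reference-standard outcomes, aligned.
#' @param cut classification threshold.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `predicted_prevalence`.
#' @export
confusion_metrics <- function(scores, outcomes, cut) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.logical(outcomes)
  pos <- scores >= cut
  tp <- sum(pos & outcomes)
  fp <- sum(pos & !outcomes)
  fn <- sum(!pos & outcomes)
  tn <- sum(!pos & !outcomes)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, fp + tn),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       predicted_prevalence = (tp + fp) / length(scores))
}

#' ROC curve points
#'
#' One `(1 - specificity, sensitivity)` point per distinct score threshold
#' (ties classify positive together, consistent with the at-or-above rule),
#' plus the `(0, 0)` and `(1, 1)` endpoints.
#'
#' @param scores numeric risk scores.
#' @param outcomes logical outcomes; both classes must be present.
#' @return data.frame `cut`, `fpr`, `tpr`, ordered from the highest cut
#'   (0, 0) to the lowest (1, 1).
#' @export
roc_points <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  if (!any(outcomes) || all(outcomes))
    stop("roc_points: need at least one positive and one negative outcome",
         call. = FALSE)
  cuts <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(outcomes)
  n_neg <- sum(!outcomes)
  tpr <- vapply(cuts, function(ct) sum(scores >= ct & outcomes) / n_pos,
                numeric(1))
  fpr <- vapply(cuts, function(ct) sum(scores >= ct & !outcomes) / n_neg,
                numeric(1))
  data.frame(cut = c(Inf, cuts, -Inf), fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_points()].
#'
#' @inheritParams roc_points
#' @return numeric scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, outcomes) {
  r <- roc_points(scores, outcomes)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

#' Select a risk-score cut point on training data
#'
#' Implements the four selection schemes: for a target-metric scheme the cut
#' must achieve the target on training data and, among those, maximize the
#' complementary metric (sensitivity targets maximize PPV; specificity and
#' PPV targets maximize sensitivity); the balanced scheme minimizes
#' `|sensitivity - PPV|`. Candidate cuts are the distinct score values; ties
#' resolve to the higher cut.
#'
#' @param train_scores,train_outcomes training-split scores and outcomes.
#' @param scheme one of `"sensitivity"`, `"specificity"`, `"ppv"`,
#'   `"balanced"`.
#' @param target target level for the metric schemes (e.g. 0.90).
#' @return the selected cut value (a score).
#' @export
select_cutpoint <- function(train_scores, train_outcomes,
                            scheme = c("sensitivity", "specificity", "ppv",
                                       "balanced"),
                            target = NULL) {
  scheme <- match.arg(scheme)
  cuts <- sort(unique(train_scores))
  m <- lapply(cuts, function(ct) confusion_metrics(train_scores,
                                                   train_outcomes, ct))
  get <- function(f) vapply(m, function(x) {
    v <- x[[f]]
    if (is.na(v)) -Inf else v
  }, numeric(1))
  if (scheme == "balanced") {
    gap <- abs(get("sensitivity") - get("ppv"))
    best <- which(gap <= min(gap) + 1e-12)
    return(cuts[max(best)])
  }
  stopifnot(!is.null(target))
  metric <- get(scheme)
  feasible <- metric >= target
  if (!any(feasible))
    stop("select_cutpoint: target ", scheme, " >= ", target,
         " unattainable on training data (best attainable: ",
         signif(max(metric), 3), ")", call. = FALSE)
  complement <- if (scheme == "sensitivity") get("ppv") else get("sensitivity")
  complement[!feasible] <- -Inf
  best <- which(complement >= max(complement) - 1e-12)
  cuts[max(best)]
}

#' ICD-9 code comparator classifier
#'
#' The simple claims algorithm used as comparator: a cohort member is
#' positive when any diagnosis code for prescription-opioid dependence,
#' abuse, or poisoning (heroin-specific codes excluded) is dated within
#' their observation window, negative otherwise.
#'
#' @param diagnoses diagnosis table for the population.
#' @param cohort cohort data.frame (for the observation windows).
#' @param code_groups named list of code prefixes; the `oud_comparator`
#'   entry defines the qualifying set.
#' @return logical vector aligned with `cohort` rows.
#' @export
icd9_classifier <- function(diagnoses, cohort,
                            code_groups = default_code_groups()) {
  hit <- code_matches(diagnoses$code, code_groups$oud_comparator)
  dxh <- diagnoses[hit, , drop = FALSE]
  by_pid <- split(dxh$date, dxh$patient_id)
  vapply(seq_len(nrow(cohort)), function(i) {
    d <- by_pid[[cohort$patient_id[i]]]
    !is.null(d) && any(d >= cohort$observation_start[i] &
                         d <= cohort$observation_end[i])
  }, logical(1))
}

#' Binomial confidence interval in percent
#'
#' Wald interval `p +/- z * sqrt(p(1-p)/n)` by default (set
#' `method = "exact"` for Clopper-Pearson via [stats::binom.test()]),
#' expressed in percent, clipped to `[0, 100]` and rounded to whole percent
#' for report display.
#'
#' @param p_hat proportion in `[0, 1]`.
#' @param n denominator (>= 1).
#' @param level confidence level (default 0.95).
#' @param method `"wald"` or `"exact"`.
#' @return numeric `c(lower, upper)` in whole percent.
#' @export
binomial_ci <- function(p_hat, n, level = 0.95, method = c("wald", "exact")) {
  method <- match.arg(method)
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 1)
  if (method == "wald") {
    z <- qnorm(1 - (1 - level) / 2)
    half <- z * sqrt(p_hat * (1 - p_hat) / n)
    ci <- c(p_hat - half, p_hat + half)
  } else {
    ci <- as.numeric(binom.test(round(p_hat * n), n,
                                conf.level = level)$conf.int)
  }
  round(pmin(pmax(ci * 100, 0), 100))
}

#' Cut-point performance report (training and validation)
#'
#' Builds the headline evaluation table: one row per cut-point scheme —
#' sensitivity, specificity and PPV targets at excellent/good/acceptable
#' levels (0.90/0.80/0.75 by default) plus the balanced
#' sensitivity-PPV scheme — and one comparator row. All cut points are
#' selected on the training split only; metrics are then reported on both
#' splits at those cuts.
#'
#' @param train_scores,train_outcomes training-split risk scores and
#'   reference outcomes.
#' @param valid_scores,valid_outcomes validation-split equivalents.
#' @param comparator optional list with logical elements `train` and
#'   `validation`: the comparator algorithm's classifications (e.g. from
#'   [icd9_classifier()]); when supplied an 11th row reports its metrics.
#' @param targets target levels for the metric schemes.
#' @return data.frame with columns `scheme`, `target`, `cut`, and
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `predicted_prevalence`
#'   for each split (suffixes `_train`, `_valid`).
#' @export
cutpoint_report <- function(train_scores, train_outcomes, valid_scores,
                          valid_outcomes, comparator = NULL,
                          targets = c(0.90, 0.80, 0.75)) {
  if (length(train_scores) == 0 || length(valid_scores) == 0)
    stop("cutpoint_report: empty split", call. = FALSE)
  rows <- list()
  metric_cols <- function(m, suffix) {
    out <- m[c("sensitivity", "specificity", "ppv", "npv",
               "predicted_prevalence")]
    names(out) <- paste0(names(out), suffix)
    out
  }
  add_row <- function(scheme, target, cut, ctrain, cvalid) {
    rows[[length(rows) + 1]] <<- data.frame(
      scheme = scheme, target = if (is.null(target)) NA_real_ else target,
      cut = cut,
      metric_cols(ctrain, "_train"), metric_cols(cvalid, "_valid"),
      stringsAsFactors = FALSE)
  }
  for (scheme in c("sensitivity", "specificity", "ppv")) {
    for (tg in targets) {
      cut <- select_cutpoint(train_scores, train_outcomes, scheme, tg)
      add_row(scheme, tg, cut,
              confusion_metrics(train_scores, train_outcomes, cut),
              confusion_metrics(valid_scores, valid_outcomes, cut))
    }
  }
  cut <- select_cutpoint(train_scores, train_outcomes, "balanced")
  add_row("balanced", NULL, cut,
          confusion_metrics(train_scores, train_outcomes, cut),
          confusion_metrics(valid_scores, valid_outcomes, cut))
  if (!is.null(comparator)) {
    ctr <- confusion_metrics(as.numeric(comparator$train), train_outcomes, 1)
    cva <- confusion_metrics(as.numeric(comparator$validation),
                             valid_outcomes, 1)
    add_row("icd9_comparator", NULL, NA_real_, ctr, cva)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
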