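#' Run the full algorithm-development pipeline
#'
#' Convenience wrapper chaining every stage: simulate (or accept) a claims
#' population, build the eligible cohort, draw the (optionally enriched)
#' analysis sample with design weights, split 70/30 into training and
#' validation, operationalize the predictor library, fit the adaptive LASSO
#' on the training split, score both splits, and produce the cut-point
#' report with the ICD-9 comparator plus design-weighted prevalence
#' estimates.
#'
#' @param population a `claims_population`, or NULL to simulate one from
#'   `config`.
#' @param config a [sim_config()] (used when `population` is NULL).
#' @param eligibility an [eligibility_config()].
#' @param specs predictor library (default [default_predictor_library()]).
#' @param penalty a [penalty_config()].
#' @param n_sample analysis sample size; `NULL` (default) takes the whole
#'   cohort as a census with unit weights, otherwise an enriched stratified
#'   sample of this size is drawn.
#' @param train_fraction training fraction of the sample (default 0.7).
#' @param seed integer seed governing sampling, the split, and
#'   cross-validation folds.
#' @return list of class `probuse_pipeline` with elements `population`,
#'   `cohort`, `strata`, `design`, `split`, `matrix`, `fit`, `scores`,
#'   `report`, `auc`, `prevalence`.
#' @export
run_pipeline <- function(population = NULL, config = sim_config(),
                         eligibility = eligibility_config(),
                         specs = default_predictor_library(),
                         penalty = penalty_config(),
                         n_sample = NULL, train_fraction = 0.7, seed = 1L) {
  if (is.null(population)) population <- generate_population(config)
  cohort <- build_cohort(population, eligibility)
  if (nrow(cohort) == 0)
    stop("run_pipeline: empty cohort", call. = FALSE)
  strata <- assign_strata(cohort, population$demographics,
                          population$diagnoses)
  if (is.null(n_sample)) {
    design <- data.frame(patient_id = cohort$patient_id,
                         stratum_id = strata$stratum_id,
                         selection_probability = 1, design_weight = 1,
                         stringsAsFactors = FALSE)
  } else {
    fr <- enrichment_fractions(strata, n_sample)
    design <- draw_stratified_sample(strata, fr, n_target = n_sample,
                                     seed = seed)
  }
  design$split <- split_train_validation(design$patient_id, train_fraction,
                                         seed = seed + 1L)
  sampled <- cohort[match(design$patient_id, cohort$patient_id), ,
                    drop = FALSE]
  X <- build_matrix(population, sampled, specs)
  y <- sampled$outcome_36m
  tr <- design$split == "train"

  penalty$fold_seed <- if (is.null(penalty$fold_seed)) seed + 2L else
    penalty$fold_seed
  fit <- fit_adaptive_lasso(X[tr, , drop = FALSE], y[tr], penalty)
  scores <- predict_risk(fit, X)
  comparator_all <- icd9_classifier(population$diagnoses, sampled)
  report <- cutpoint_report(scores[tr], y[tr], scores[!tr], y[!tr],
                          comparator = list(train = comparator_all[tr],
                                            validation = comparator_all[!tr]))
  out <- list(
    population = population, cohort = cohort, strata = strata,
    design = design, split = design$split, matrix = X, fit = fit,
    scores = scores, outcomes = y, comparator = comparator_all,
    report = report,
    auc = list(train = roc_auc(scores[tr], y[tr]),
               validation = roc_auc(scores[!tr], y[!tr])),
    prevalence = list(
      sample = mean(y),
      weighted = weighted_prevalence(y, design$design_weight),
      pool = mean(cohort$outcome_36m)))
  class(out) <- "probuse_pipeline"
  out
}

#' @export
print.probuse_pipeline <- function(x, ...) {
  cat("<probuse_pipeline>\n")
  cat("  cohort:", nrow(x$cohort), "eligible patients;",
      sum(x$design$split == "train"), "train /",
      sum(x$design$split == "validation"), "validation\n")
  cat("  model:", length(x$fit$retained), "of", ncol(x$matrix),
      "predictors retained (gamma =", x$fit$gamma,
      ", lambda =", signif(x$fit$lambda, 3), ")\n")
  cat("  AUC: train", round(x$auc$train, 3), "/ validation",
      round(x$auc$validation, 3), "\n")
  cat("  weighted 36-month prevalence:",
      round(100 * x$prevalence$weighted, 1), "%\n")
  invisible(x)
}
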