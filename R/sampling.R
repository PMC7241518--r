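#' Assign enrichment strata
#'
#' Crosses the two enrichment axes used for sampling: age at the index date
#' (18–34 vs 35+) and presence of any opioid dependence/abuse/poisoning
#' diagnosis code during the study period. Heroin-specific poisoning codes do
#' not count toward the code stratum (the comparator code list excludes
#' heroin).
#'
#' @param cohort cohort data.frame from [build_cohort()].
#' @param demographics demographics table (for birth dates).
#' @param diagnoses diagnosis table for the whole study period.
#' @param code_groups named list of code prefixes; the `oud_comparator` entry
#'   defines the enrichment codes (see [default_code_groups()]).
#' @return data.frame `patient_id`, `age_stratum`, `oud_code_stratum`,
#'   `stratum_id`.
#' @export
assign_strata <- function(cohort, demographics, diagnoses,
                          code_groups = default_code_groups()) {
  codes <- diagnoses$code
  bad <- !grepl("^[0-9EV]", codes)
  if (any(bad))
    stop("assign_strata: unparseable diagnosis code(s): ",
         paste(unique(codes[bad])[1:min(3, sum(bad))], collapse = ", "),
         call. = FALSE)
  birth <- demographics$birth_date[match(cohort$patient_id, demographics$patient_id)]
  age <- age_at(birth, cohort$index_date)
  age_stratum <- ifelse(age < 35, "18-34", "35+")
  hit <- code_matches(codes, code_groups$oud_comparator)
  flagged <- unique(diagnoses$patient_id[hit])
  oud_code_stratum <- cohort$patient_id %in% flagged
  data.frame(patient_id = cohort$patient_id,
             age_stratum = age_stratum,
             oud_code_stratum = oud_code_stratum,
             stratum_id = paste0(age_stratum, "/",
                                 ifelse(oud_code_stratum, "oud", "no_oud")),
             stringsAsFactors = FALSE)
}

#' Enrichment sampling fractions for a target sample size
#'
#' Convenience constructor for the oversampling design: enriched strata
#' (age 18–34 or any OUD code) are sampled completely, and the remaining
#' target is drawn proportionally from the non-enriched stratum.
#'
#' @param strata output of [assign_strata()].
#' @param n_target total intended sample size.
#' @return named numeric vector of per-stratum sampling fractions.
#' @export
enrichment_fractions <- function(strata, n_target) {
  sizes <- table(strata$stratum_id)
  enriched <- grepl("^18-34|/oud$", names(sizes))
  n_enriched <- sum(sizes[enriched])
  if (n_enriched >= n_target)
    stop("enrichment_fractions: enriched strata alone exceed n_target",
         call. = FALSE)
  remainder <- n_target - n_enriched
  frac <- ifelse(enriched, 1, min(1, remainder / sum(sizes[!enriched])))
  stats::setNames(as.numeric(frac), names(sizes))
}

#' Draw a stratified sample with design weights
#'
#' Samples without replacement within each stratum at the configured
#' fraction, recording each sampled patient's selection probability and its
#' inverse (the design weight used to re-weight estimates back to the
#' eligible pool).
#'
#' @param strata output of [assign_strata()].
#' @param fractions named numeric vector of sampling fractions per
#'   `stratum_id` (a single unnamed number recycles to all strata).
#' @param n_target optional; when given, a warning is issued if the expected
#'   sample size differs from it by more than 1%.
#' @param seed optional integer seed (seeds the global RNG).
#' @return data.frame `patient_id`, `stratum_id`, `selection_probability`,
#'   `design_weight`.
#' @export
draw_stratified_sample <- function(strata, fractions, n_target = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(strata$stratum_id)
  if (length(fractions) == 1 && is.null(names(fractions)))
    fractions <- stats::setNames(rep(fractions, length(ids)), ids)
  if (!all(ids %in% names(fractions)))
    stop("draw_stratified_sample: no sampling fraction for stratum ",
         paste(setdiff(ids, names(fractions)), collapse = ", "), call. = FALSE)
  if (any(fractions < 0 | fractions > 1))
    stop("draw_stratified_sample: fractions must be in [0, 1]", call. = FALSE)
  if (!is.null(n_target)) {
    expected <- sum(vapply(ids, function(s)
      fractions[[s]] * sum(strata$stratum_id == s), numeric(1)))
    if (abs(expected - n_target) > 0.01 * n_target)
      warning("expected sample size ", round(expected),
              " differs from n_target ", n_target)
  }
  out <- list()
  for (s in ids) {
    members <- strata$patient_id[strata$stratum_id == s]
    n_h <- round(length(members) * fractions[[s]])
    if (n_h > length(members))
      stop("draw_stratified_sample: requested more than stratum size in ", s,
           call. = FALSE)
    if (n_h == 0) next
    chosen <- if (length(members) == 1 && n_h == 1) members else
      sample(members, n_h)
    p <- n_h / length(members)
    out[[s]] <- data.frame(patient_id = chosen, stratum_id = s,
                           selection_probability = p, design_weight = 1 / p,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(match(res$patient_id, strata$patient_id)), , drop = FALSE]
}

#' Split a sample into training and validation sets
#'
#' Random assignment of exactly `round(n * train_fraction)` patients to the
#' training split and the remainder to validation.
#'
#' @param patient_ids character vector of sampled patient ids.
#' @param train_fraction fraction assigned to training (default 0.7).
#' @param seed optional integer seed.
#' @return character vector (`"train"`/`"validation"`) aligned with
#'   `patient_ids`.
#' @export
split_train_validation <- function(patient_ids, train_fraction = 0.7,
                                   seed = NULL) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("split_train_validation: train_fraction must be in (0, 1)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(patient_ids)
  n_train <- round(n * train_fraction)
  split <- rep("validation", n)
  split[sample.int(n, n_train)] <- "train"
  split
}

#' Design-weighted prevalence
#'
#' Horvitz–Thompson style estimate of the eligible-pool prevalence from an
#' enriched sample: `sum(w * y) / sum(w)`.
#'
#' @param labels logical (or 0/1) outcome vector.
#' @param weights positive design weights (default all 1: the sample
#'   proportion).
#' @return estimated prevalence in `[0, 1]`.
#' @export
weighted_prevalence <- function(labels, weights = NULL) {
  if (length(labels) == 0)
    stop("weighted_prevalence: empty input", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(labels))
  if (length(weights) != length(labels))
    stop("weighted_prevalence: labels and weights differ in length",
         call. = FALSE)
  if (any(weights <= 0))
    stop("weighted_prevalence: weights must be > 0", call. = FALSE)
  sum(weights * as.numeric(labels)) / sum(weights)
}
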