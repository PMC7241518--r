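#' The shipped predictor spec library
#'
#' A curated, documented library of roughly 110 predictor specs spanning
#' every candidate-variable family of the development study: diagnosis
#' groups (pain sites, mental health, problem opioid use, non-opioid
#' substance use, sleep, psycho-social trauma, hepatitis, endocarditis,
#' adverse-effect E-codes) as ever/never flags and percent-of-quarters;
#' days'-supply totals and per-grain aggregates by drug class with
#' excess-supply variants; MEQ summaries (mean, per-supply-day, max,
#' threshold exceedances at 50/90/120 MEQ/day, consecutive-quarter percent
#' change at 33/50/75%); overlapping-fill variants; concomitant
#' opioid/psychoactive use; ER encounters during exposure; urine-drug-screen
#' counts and proximity; OUD-treatment medications; a simplified Charlson
#' index; demographics; and age-group interactions. Coverage is by family,
#' not a reconstruction of the original 1,126-variable catalog; the library
#' is a starting point meant to be extended with [predictor_spec()].
#'
#' @param code_groups named list of diagnosis code prefixes
#'   (default [default_code_groups()]).
#' @param meq_thresholds "high MEQ" thresholds in MEQ/day.
#' @param change_fracs consecutive-quarter percent-change thresholds.
#' @return named list of [predictor_spec()] objects.
#' @export
default_predictor_library <- function(code_groups = default_code_groups(),
                                      meq_thresholds = c(50, 90, 120),
                                      change_fracs = c(0.33, 0.50, 0.75)) {
  cg <- code_groups
  sp <- list()
  add <- function(s) sp[[s$name]] <<- s

  dx_groups <- c("pain_back", "pain_neck", "headache", "neuropathic_pain",
                 "fibromyalgia", "arthritis", "depression", "anxiety",
                 "bipolar", "schizophrenia", "other_mental_health", "ptsd",
                 "domestic_violence", "opioid_dependence", "opioid_abuse",
                 "opioid_poisoning", "heroin", "alcohol_disorder",
                 "cannabis_dependence", "other_drug_dependence",
                 "nondependent_abuse", "tobacco", "sleep_disorder",
                 "hepatitis_cirrhosis", "endocarditis", "adverse_drug_ecodes")
  for (g in dx_groups) {
    add(predictor_spec(paste0("dx_", g, "_ever"), "diagnosis_flag",
                       list(codes = cg[[g]]), "binary"))
    add(predictor_spec(paste0("dx_", g, "_pct_quarters"), "pct_quarters",
                       list(codes = cg[[g]]), "proportion"))
  }
  for (g in c("opioid_dependence", "opioid_abuse", "opioid_poisoning"))
    add(predictor_spec(paste0("dx_", g, "_count"), "diagnosis_count",
                       list(codes = cg[[g]], grain = "overall"), "count"))
  add(predictor_spec("dx_pain_site_count", "pain_site_count",
                     list(groups = cg[c("pain_back", "pain_neck", "headache",
                                        "neuropathic_pain", "fibromyalgia",
                                        "arthritis")]), "count"))

  for (cl in list(c("ERLA_opioid"), c("IR_opioid"),
                  c("ERLA_opioid", "IR_opioid"))) {
    tag <- paste(sub("_opioid", "", cl), collapse = "_")
    add(predictor_spec(paste0("supply_", tag, "_total"), "days_supply_agg",
                       list(classes = cl, grain = "overall"), "continuous"))
    add(predictor_spec(paste0("supply_", tag, "_per_quarter"), "days_supply_agg",
                       list(classes = cl, grain = "quarter"), "continuous"))
    add(predictor_spec(paste0("supply_", tag, "_per_month"), "days_supply_agg",
                       list(classes = cl, grain = "month"), "continuous"))
  }
  add(predictor_spec("supply_benzo_total", "days_supply_agg",
                     list(classes = "benzodiazepine", grain = "overall"),
                     "continuous"))
  add(predictor_spec("supply_psychoactive_total", "days_supply_agg",
                     list(classes = c("benzodiazepine", "other_psychoactive"),
                          grain = "overall"), "continuous"))
  add(predictor_spec("supply_opioid_excess_quarters", "days_supply_agg",
                     list(classes = c("ERLA_opioid", "IR_opioid"),
                          stat = "excess_quarters", threshold = 100), "count"))
  add(predictor_spec("supply_opioid_excess_ever", "days_supply_agg",
                     list(classes = c("ERLA_opioid", "IR_opioid"),
                          stat = "excess_flag", threshold = 100), "binary"))

  add(predictor_spec("meq_mean_daily", "meq_measure",
                     list(stat = "mean_daily"), "continuous"))
  add(predictor_spec("meq_per_supply_day", "meq_measure",
                     list(stat = "per_supply_day"), "continuous"))
  add(predictor_spec("meq_max_daily", "meq_measure",
                     list(stat = "max_daily"), "continuous"))
  for (t in meq_thresholds) {
    add(predictor_spec(paste0("meq_days_ge_", t), "meq_measure",
                       list(stat = "days_ge", threshold = t), "count"))
    add(predictor_spec(paste0("meq_pct_quarters_ge_", t), "meq_measure",
                       list(stat = "pct_quarters_ge", threshold = t),
                       "proportion"))
  }
  for (f in change_fracs)
    add(predictor_spec(paste0("meq_change_ge_", round(100 * f)), "meq_measure",
                       list(stat = "change_ge", frac = f), "binary"))

  add(predictor_spec("overlap_ir_weekend", "overlap_fills",
                     list(class_filter = "IR_opioid", max_days_supply = 14,
                          dow_set = c("Sat", "Sun", "Mon"),
                          window_len_months = 3, min_fills = 3), "binary"))
  add(predictor_spec("overlap_ir_any_dow", "overlap_fills",
                     list(class_filter = "IR_opioid", max_days_supply = 14,
                          dow_set = NULL, window_len_months = 3,
                          min_fills = 3), "binary"))
  add(predictor_spec("overlap_ir_chain_size", "overlap_fills",
                     list(class_filter = "IR_opioid", max_days_supply = 14,
                          dow_set = NULL, window_len_months = 3,
                          value = "count"), "count"))
  add(predictor_spec("overlap_erla", "overlap_fills",
                     list(class_filter = "ERLA_opioid", max_days_supply = Inf,
                          dow_set = NULL, window_len_months = 3,
                          min_fills = 3), "binary"))
  add(predictor_spec("overlap_any_opioid", "overlap_fills",
                     list(class_filter = c("ERLA_opioid", "IR_opioid"),
                          max_days_supply = Inf, dow_set = NULL,
                          window_len_months = 3, min_fills = 3), "binary"))
  add(predictor_spec("overlap_any_opioid_chain_size", "overlap_fills",
                     list(class_filter = c("ERLA_opioid", "IR_opioid"),
                          max_days_supply = Inf, dow_set = NULL,
                          window_len_months = 3, value = "count"), "count"))

  add(predictor_spec("concomitant_days", "concomitant_use",
                     list(stat = "days"), "count"))
  add(predictor_spec("concomitant_ever", "concomitant_use",
                     list(stat = "flag"), "binary"))
  add(predictor_spec("concomitant_pct_quarters", "concomitant_use",
                     list(stat = "pct_quarters"), "proportion"))

  add(predictor_spec("er_visits", "er_during_exposure",
                     list(condition = "any"), "count"))
  add(predictor_spec("er_ever", "er_during_exposure",
                     list(condition = "any", value = "flag"), "binary"))
  add(predictor_spec("er_during_opioid_coverage", "er_during_exposure",
                     list(condition = "opioid_coverage"), "count"))
  add(predictor_spec("er_during_overlap", "er_during_exposure",
                     list(condition = "overlap"), "count"))
  add(predictor_spec("er_during_high_meq", "er_during_exposure",
                     list(condition = "high_meq", threshold = 90), "count"))

  add(predictor_spec("uds_count", "procedure_proximity",
                     list(category = "urine_drug_screen", stat = "count"),
                     "count"))
  add(predictor_spec("uds_pct_quarters", "procedure_proximity",
                     list(category = "urine_drug_screen",
                          stat = "pct_quarters"), "proportion"))
  add(predictor_spec("uds_near_overlap", "procedure_proximity",
                     list(category = "urine_drug_screen", stat = "near_overlap",
                          k = 7), "count"))
  add(predictor_spec("uds_near_high_meq", "procedure_proximity",
                     list(category = "urine_drug_screen",
                          stat = "near_high_meq", k = 7, threshold = 90),
                     "count"))
  add(predictor_spec("sud_treatment_proc_ever", "procedure_proximity",
                     list(category = "SUD_treatment", stat = "flag"), "binary"))
  add(predictor_spec("surgery_count", "procedure_proximity",
                     list(category = "surgery", stat = "count"), "count"))

  add(predictor_spec("oud_treatment_ever", "oud_treatment_med",
                     list(stat = "ever"), "binary"))
  add(predictor_spec("oud_treatment_days_supply", "oud_treatment_med",
                     list(stat = "days_supply"), "continuous"))

  add(predictor_spec("charlson_index", "charlson",
                     list(code_groups = cg), "count"))

  add(predictor_spec("age_at_index", "demographic", list(var = "age"),
                     "continuous"))
  add(predictor_spec("age_18_34", "demographic", list(var = "age_18_34"),
                     "binary"))
  add(predictor_spec("age_ge_65", "demographic", list(var = "age_ge_65"),
                     "binary"))
  add(predictor_spec("sex_female", "demographic", list(var = "sex_female"),
                     "binary"))

  young_x <- list(
    overlap = sp[["overlap_ir_weekend"]],
    oud_dx = sp[["dx_opioid_dependence_ever"]],
    high_meq = predictor_spec("meq_days_ge_90_base", "meq_measure",
                              list(stat = "days_ge", threshold = 90), "count"),
    concomitant = sp[["concomitant_ever"]])
  for (nm in names(young_x))
    add(predictor_spec(paste0("ix_age_18_34_x_", nm), "interaction",
                       list(age_group = "18-34", base = young_x[[nm]]),
                       "continuous"))
  sp
}
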