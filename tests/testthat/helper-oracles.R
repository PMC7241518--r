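# Fixture builders and independent brute-force oracles used across tests.

make_dispensings <- function(dates, supplies, class = "ERLA_opioid",
                             quantity = NULL, mg = 10, meq = 1,
                             drug_code = "ERLA001", patient_id = "P000001") {
  dates <- as.Date(dates)
  if (length(dates) == 0) return(probuse:::empty_population()$dispensings)
  if (is.null(quantity)) quantity <- supplies
  data.frame(patient_id = patient_id, dispense_date = dates,
             drug_code = drug_code, drug_class = class,
             days_supply = supplies, quantity = quantity, mg_per_unit = mg,
             meq_factor = ifelse(class %in% c("ERLA_opioid", "IR_opioid"),
                                 meq, NA_real_),
             stringsAsFactors = FALSE)
}

make_spans <- function(starts, ends, patient_id = "P000001") {
  data.frame(patient_id = patient_id, start_date = as.Date(starts),
             end_date = as.Date(ends), stringsAsFactors = FALSE)
}

# Daily-grid oracle for the index date: scan every candidate day, find the
# earliest qualifying window, return the first fill date inside it.
oracle_index_date <- function(dispensings, min_supply = 60, window_len = 90) {
  erla <- dispensings[dispensings$drug_class == "ERLA_opioid", , drop = FALSE]
  if (nrow(erla) == 0) return(as.Date(NA))
  days <- seq(min(erla$dispense_date) - window_len, max(erla$dispense_date),
              by = "day")
  for (t in as.numeric(days)) {
    t <- as.Date(t, origin = "1970-01-01")
    tot <- sum(erla$days_supply[erla$dispense_date >= t &
                                  erla$dispense_date <= t + window_len - 1])
    if (tot >= min_supply) return(min(erla$dispense_date[erla$dispense_date >= t]))
  }
  as.Date(NA)
}

# POSIXlt-based weekday names, independent of the package's epoch formula.
oracle_weekday <- function(dates) {
  c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[as.POSIXlt(dates)$wday + 1]
}

# Brute-force overlap-chain oracle: expand fills to explicit coverage-day
# sets, enumerate all subsets of size `min_fills`, and flag when some
# subset lies within a rolling span and forms a connected overlap graph.
oracle_overlap_flag <- function(dispensings, class_filter = "IR_opioid",
                                max_days_supply = 14,
                                dow_set = c("Sat", "Sun", "Mon"),
                                window_len_months = 3, min_fills = 3) {
  q <- dispensings[dispensings$drug_class %in% class_filter &
                     dispensings$days_supply <= max_days_supply, ,
                   drop = FALSE]
  if (!is.null(dow_set))
    q <- q[oracle_weekday(q$dispense_date) %in% dow_set, , drop = FALSE]
  if (nrow(q) < min_fills) return(FALSE)
  cov <- lapply(seq_len(nrow(q)), function(i)
    as.numeric(seq(q$dispense_date[i],
                   q$dispense_date[i] + q$days_supply[i] - 1, by = "day")))
  subsets <- utils::combn(nrow(q), min_fills)
  for (k in seq_len(ncol(subsets))) {
    s <- subsets[, k]
    dts <- q$dispense_date[s]
    if (max(dts) > add_months(min(dts), window_len_months) - 1) next
    adj <- matrix(FALSE, min_fills, min_fills)
    for (a in seq_len(min_fills))
      for (b in seq_len(min_fills))
        adj[a, b] <- length(intersect(cov[[s[a]]], cov[[s[b]]])) > 0
    reach <- adj
    for (step in seq_len(min_fills))
      reach <- reach | ((reach %*% adj) > 0)
    if (all(reach)) return(TRUE)
  }
  FALSE
}

# Exhaustive cut-point oracle: evaluate every distinct score as a cut.
oracle_cutpoint <- function(scores, outcomes, scheme, target = NULL) {
  cuts <- sort(unique(scores))
  stats <- lapply(cuts, function(ct) confusion_metrics(scores, outcomes, ct))
  val <- function(f) vapply(stats, function(x)
    ifelse(is.na(x[[f]]), -Inf, x[[f]]), numeric(1))
  if (scheme == "balanced") {
    gap <- abs(val("sensitivity") - val("ppv"))
    return(cuts[max(which(gap <= min(gap) + 1e-12))])
  }
  ok <- val(scheme) >= target
  if (!any(ok)) return(NULL)
  comp <- if (scheme == "sensitivity") val("ppv") else val("sensitivity")
  comp[!ok] <- -Inf
  cuts[max(which(comp >= max(comp) - 1e-12))]
}

# Random small dispensing set for oracle-agreement property tests
# (consumes the ambient RNG stream).
random_fill_set <- function(max_fills = 8) {
  n <- sample(0:max_fills, 1)
  base <- as.Date("2010-01-01") + sample(0:300, 1)
  if (n == 0) return(make_dispensings(as.Date(character(0)), numeric(0)))
  make_dispensings(base + sample(0:180, n, replace = TRUE),
                   sample(c(5, 7, 10, 14, 28, 30, 90), n, replace = TRUE),
                   class = sample(c("ERLA_opioid", "IR_opioid"), n,
                                  replace = TRUE))
}

# Minimal cohort-member row for direct predictor evaluation.
make_member <- function(index_date, patient_id = "P000001",
                        pre_months = 12, post_months = 24) {
  index_date <- as.Date(index_date)
  data.frame(patient_id = patient_id, index_date = index_date,
             observation_start = add_months(index_date, -pre_months),
             observation_end = add_months(index_date, post_months) - 1,
             outcome_36m = FALSE, stringsAsFactors = FALSE)
}

# Minimal population container around hand-built tables.
make_population <- function(dispensings = NULL, diagnoses = NULL,
                            encounters = NULL, procedures = NULL,
                            demographics = NULL, labels = NULL,
                            enrollment = NULL) {
  empty <- probuse:::empty_population()
  pop <- list(
    demographics = if (is.null(demographics)) empty$demographics else demographics,
    enrollment = if (is.null(enrollment)) empty$enrollment else enrollment,
    encounters = if (is.null(encounters)) empty$encounters else encounters,
    diagnoses = if (is.null(diagnoses)) empty$diagnoses else diagnoses,
    procedures = if (is.null(procedures)) empty$procedures else procedures,
    dispensings = if (is.null(dispensings)) empty$dispensings else dispensings,
    labels = if (is.null(labels)) empty$labels else labels)
  class(pop) <- "claims_population"
  pop
}

make_demographics <- function(patient_id = "P000001",
                              birth_date = "1960-06-15", sex = "F",
                              race = "White", excluded = FALSE) {
  data.frame(patient_id = patient_id, birth_date = as.Date(birth_date),
             sex = sex, race = race, excluded = excluded,
             stringsAsFactors = FALSE)
}
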