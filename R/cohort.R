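#' Cohort eligibility configuration
#'
#' Parameters of the study-eligibility algorithm: a patient qualifies when
#' they receive at least `min_days_supply` days' supply of ER/LA opioids
#' within a `window_len`-day window, have continuous enrollment covering at
#' least `pre_index_months` before and `post_index_months` after the index
#' date (gaps up to `gap_tolerance` days bridged), and have encounters in at
#' least `min_encounter_quarters` distinct calendar quarters. The
#' observation window runs from `obs_pre_months` before to `obs_post_months`
#' after the index date.
#'
#' @param min_days_supply days' supply of ER/LA opioid required (default 60).
#' @param window_len qualification window length in calendar days
#'   (default 90; the window is closed, `[d, d + window_len - 1]`).
#' @param pre_index_months,post_index_months,total_enrollment_months
#'   continuous-enrollment requirements around the index date (6/18/24).
#' @param min_encounter_quarters distinct calendar quarters with at least one
#'   encounter (default 8).
#' @param gap_tolerance enrollment gaps up to this many days are bridged
#'   (default 0; 30 is common claims practice).
#' @param obs_pre_months,obs_post_months observation window around the index
#'   date (12/24 months: a 36-month window).
#' @return object of class `eligibility_config`.
#' @export
eligibility_config <- function(min_days_supply = 60, window_len = 90,
                               pre_index_months = 6, post_index_months = 18,
                               total_enrollment_months = 24,
                               min_encounter_quarters = 8,
                               gap_tolerance = 0,
                               obs_pre_months = 12, obs_post_months = 24) {
  cfg <- list(min_days_supply = min_days_supply, window_len = window_len,
              pre_index_months = pre_index_months,
              post_index_months = post_index_months,
              total_enrollment_months = total_enrollment_months,
              min_encounter_quarters = min_encounter_quarters,
              gap_tolerance = gap_tolerance,
              obs_pre_months = obs_pre_months,
              obs_post_months = obs_post_months)
  vals <- unlist(cfg[setdiff(names(cfg), "gap_tolerance")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("eligibility_config: all values must be positive", call. = FALSE)
  if (cfg$gap_tolerance < 0)
    stop("eligibility_config: gap_tolerance must be >= 0", call. = FALSE)
  if (cfg$pre_index_months + cfg$post_index_months > cfg$total_enrollment_months)
    stop("eligibility_config: pre + post enrollment months exceed total",
         call. = FALSE)
  class(cfg) <- "eligibility_config"
  cfg
}

#' ER/LA index date
#'
#' The index date is the first ER/LA opioid dispense date `d` such that the
#' summed ER/LA days' supply dispensed in the closed window
#' `[d, d + window_len - 1]` reaches `min_days_supply`. Only fills of class
#' `ERLA_opioid` count (buprenorphine-type products are classed
#' `OUD_treatment` and never qualify); supply counts toward a window by
#' dispense date, not by coverage-day attribution. Candidate windows are
#' anchored at fill dates, which is equivalent to a daily-grid search for the
#' returned index.
#'
#' @param dispensings data.frame of dispensing records for one patient
#'   (columns `dispense_date`, `drug_class`, `days_supply`).
#' @param config an [eligibility_config()].
#' @return the index `Date`, or `NA` if no window qualifies.
#' @export
find_index_date <- function(dispensings, config = eligibility_config()) {
  if (any(dispensings$days_supply < 0, na.rm = TRUE))
    stop("find_index_date: negative days_supply in dispensing data",
         call. = FALSE)
  erla <- dispensings[dispensings$drug_class == "ERLA_opioid", , drop = FALSE]
  if (nrow(erla) == 0) return(as.Date(NA))
  erla <- erla[order(erla$dispense_date), , drop = FALSE]
  d <- erla$dispense_date
  s <- erla$days_supply
  for (i in seq_along(d)) {
    in_win <- d >= d[i] & d <= d[i] + (config$window_len - 1)
    if (sum(s[in_win]) >= config$min_days_supply) return(d[i])
  }
  as.Date(NA)
}

#' Continuous-enrollment check around the index date
#'
#' TRUE when a single enrollment span — after bridging gaps of at most
#' `gap_tolerance` days — covers the interval from `pre_index_months` before
#' to `post_index_months` after the index date and lasts at least
#' `total_enrollment_months` calendar months.
#'
#' @param spans data.frame with `start_date`, `end_date` (non-overlapping).
#' @param index_date the patient's index `Date`.
#' @param config an [eligibility_config()].
#' @return logical scalar.
#' @export
check_continuous_enrollment <- function(spans, index_date,
                                        config = eligibility_config()) {
  if (is.na(index_date) || nrow(spans) == 0) return(FALSE)
  merged <- merge_spans(spans, config$gap_tolerance)
  lo <- add_months(index_date, -config$pre_index_months)
  hi <- add_months(index_date, config$post_index_months)
  covering <- merged$start_date <= lo & merged$end_date >= hi
  long_enough <- add_months(merged$start_date, config$total_enrollment_months) - 1 <=
    merged$end_date
  any(covering & long_enough)
}

# Merge sorted spans, bridging gaps of at most `tolerance` days.
merge_spans <- function(spans, tolerance = 0) {
  spans <- spans[order(spans$start_date), , drop = FALSE]
  out_start <- spans$start_date[1]
  out_end <- spans$end_date[1]
  starts <- ends <- list()
  for (k in seq_len(nrow(spans))[-1]) {
    gap <- as.numeric(spans$start_date[k] - out_end) - 1
    if (gap <= tolerance) {
      out_end <- max(out_end, spans$end_date[k])
    } else {
      starts[[length(starts) + 1]] <- out_start
      ends[[length(ends) + 1]] <- out_end
      out_start <- spans$start_date[k]
      out_end <- spans$end_date[k]
    }
  }
  starts[[length(starts) + 1]] <- out_start
  ends[[length(ends) + 1]] <- out_end
  data.frame(start_date = do.call(c, starts), end_date = do.call(c, ends))
}

#' Count calendar quarters containing at least one encounter
#'
#' @param encounters data.frame with a `date` column (one patient).
#' @param study_period optional `c(start, end)` Dates; encounters outside it
#'   are ignored.
#' @return integer count of distinct calendar quarters.
#' @export
count_encounter_quarters <- function(encounters, study_period = NULL) {
  d <- encounters$date
  if (!is.null(study_period)) d <- d[d >= study_period[1] & d <= study_period[2]]
  length(unique(quarter_id(d[!is.na(d)])))
}

#' Build the study cohort
#'
#' Applies the eligibility algorithm to a claims population: age >= 18 at
#' study start, no nursing-home/hospice exclusion flag, a qualifying ER/LA
#' index date, continuous enrollment around it, and the minimum number of
#' encounter quarters. For members, the 36-month observation window is
#' `observation_start = index - obs_pre_months` months through
#' `observation_end = index + obs_post_months months - 1 day`, and the
#' reference-standard outcome is operationalized against it: positive when
#' the documented onset falls on or before `observation_end` (onsets *before*
#' the window also count as positive), negative when there is no onset or it
#' falls after the window.
#'
#' @param population a `claims_population` (or compatible list of tables).
#' @param config an [eligibility_config()].
#' @param keep_all if TRUE, return one row per evaluated patient with all
#'   eligibility flags (audit mode); member fields are `NA` for
#'   non-members. Default FALSE returns members only.
#' @return data.frame with `patient_id`, `index_date`, `observation_start`,
#'   `observation_end`, `outcome_36m` and per-criterion eligibility flags.
#' @export
build_cohort <- function(population, config = eligibility_config(),
                         keep_all = FALSE) {
  demo <- population$demographics
  study_start <- if (!is.null(population$config)) population$config$study_start else
    min(population$enrollment$start_date, na.rm = TRUE)
  study_end <- if (!is.null(population$config)) population$config$study_end else
    max(population$enrollment$end_date, na.rm = TRUE)

  disp_by <- split_by_patient(population$dispensings, demo$patient_id)
  enr_by <- split_by_patient(population$enrollment, demo$patient_id)
  enc_by <- split_by_patient(population$encounters, demo$patient_id)

  n <- nrow(demo)
  index_date <- as.Date(rep(NA, n))
  flag_age <- age_at(demo$birth_date, study_start) >= 18
  flag_not_excluded <- !demo$excluded
  flag_index <- flag_enroll <- flag_quarters <- rep(FALSE, n)
  for (i in seq_len(n)) {
    pid <- demo$patient_id[i]
    idx <- find_index_date(disp_by[[pid]], config)
    index_date[i] <- idx
    flag_index[i] <- !is.na(idx)
    if (!is.na(idx))
      flag_enroll[i] <- check_continuous_enrollment(enr_by[[pid]], idx, config)
    flag_quarters[i] <- count_encounter_quarters(enc_by[[pid]],
                                                 c(study_start, study_end)) >=
      config$min_encounter_quarters
  }
  eligible <- flag_age & flag_not_excluded & flag_index & flag_enroll & flag_quarters

  obs_start <- add_months(index_date, -config$obs_pre_months)
  obs_end <- add_months(index_date, config$obs_post_months) - 1

  labels <- population$labels
  lab_idx <- match(demo$patient_id, labels$patient_id)
  missing_lab <- eligible & is.na(lab_idx)
  if (any(missing_lab))
    stop("build_cohort: missing reference label for eligible patient(s): ",
         paste(demo$patient_id[missing_lab], collapse = ", "), call. = FALSE)
  onset <- labels$onset_date[lab_idx]
  positive <- labels$problem_use[lab_idx]
  outcome <- !is.na(positive) & positive & !is.na(onset) & onset <= obs_end

  out <- data.frame(
    patient_id = demo$patient_id,
    index_date = index_date,
    observation_start = obs_start,
    observation_end = obs_end,
    outcome_36m = outcome,
    eligible_age = flag_age,
    eligible_not_excluded = flag_not_excluded,
    eligible_index = flag_index,
    eligible_enrollment = flag_enroll,
    eligible_encounters = flag_quarters,
    stringsAsFactors = FALSE)
  if (keep_all) {
    out$eligible <- eligible
    out$outcome_36m[!eligible] <- NA
    return(out)
  }
  out[eligible, , drop = FALSE]
}

# Split a table into a per-patient list covering every id in `ids`
# (patients with no rows get an empty table of the same shape).
split_by_patient <- function(table, ids) {
  empty <- table[0, , drop = FALSE]
  out <- split(table, factor(table$patient_id, levels = ids))
  out[vapply(out, is.null, logical(1))] <- list(empty)
  out
}
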