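#' Configuration for the synthetic claims simulator
#'
#' Defines a synthetic patient population in a simplified Sentinel-CDM-like
#' layout: demographics, enrollment spans, encounters, diagnoses, procedures,
#' medication dispensings, and a reference-standard label table with onset
#' dates. A latent problem-use trait (prevalence `latent_prevalence`) shifts
#' the intensity of configured event streams through `effect_profile`, so
#' downstream predictors carry real signal.
#'
#' All stream rates are simulator assumptions (the generator emulates the
#' *structure* of claims data, not any particular health system); see the
#' package vignette for the rationale behind each default.
#'
#' @param n_patients number of patients to simulate.
#' @param study_start,study_end study period bounds (Dates).
#' @param latent_prevalence probability of the latent problem-use trait.
#' @param effect_profile named list of positive rate multipliers applied to
#'   trait-positive patients: `early_fill` (early-refill/IR-fill intensity),
#'   `high_meq` (probability of high-strength opioid products), `oud_dx`
#'   (opioid dependence/abuse/poisoning diagnosis hazard after latent onset),
#'   `er_visit` (emergency-room encounter rate), `benzo`
#'   (benzodiazepine/psychoactive co-dispensing rate), `oud_treatment`
#'   (probability of receiving OUD-treatment medication).
#' @param neg_profile same shape, applied to trait-negative patients
#'   (default all 1). Setting an entry to 0 switches that stream off for
#'   trait-negatives.
#' @param rates named list of baseline stream intensities (per enrolled year
#'   unless noted): `ir_fill` (IR opioid fills/yr during the ER/LA episode),
#'   `ir_fill_bg` (outside the episode), `benzo_fill`, `oud_dx`, `heroin_dx`,
#'   `er_visit`, `urgent_visit`, `inpatient_visit`, `outpatient_visit`,
#'   `pain_dx`, `mh_dx`, `sleep_dx`, `comorbid_dx`, `uds`, `sud_treatment`,
#'   `surgery`; plus `oud_treatment_prob` (per-patient probability),
#'   `high_meq_prob` (per-fill probability of a high-strength product) and
#'   `early_fill_mean` (mean days an ER/LA refill arrives early).
#' @param erla_user_frac fraction of patients given a long-term ER/LA episode
#'   (keeps the cohort stage non-degenerate).
#' @param enrollment_gap_hazard expected enrollment gaps per enrolled year;
#'   gaps split one long span into several.
#' @param onset_delay_mean mean of the geometric documentation delay (days
#'   from latent onset to the chart-documented onset date).
#' @param exclusion_prob probability of the nursing-home/hospice exclusion
#'   flag.
#' @param drug_dictionary see [default_drug_dictionary()].
#' @param code_groups see [default_code_groups()].
#' @param seed integer seed; the whole population is a deterministic function
#'   of the configuration including this seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 2000,
                       study_start = as.Date("2006-01-01"),
                       study_end = as.Date("2015-06-30"),
                       latent_prevalence = 0.25,
                       effect_profile = list(),
                       neg_profile = list(),
                       rates = list(),
                       erla_user_frac = 0.9,
                       enrollment_gap_hazard = 0.05,
                       onset_delay_mean = 60,
                       exclusion_prob = 0.02,
                       drug_dictionary = default_drug_dictionary(),
                       code_groups = default_code_groups(),
                       seed = 1L) {
  default_profile <- list(early_fill = 3, high_meq = 3, oud_dx = 20,
                          er_visit = 3, benzo = 2.5, oud_treatment = 10)
  unit_profile <- lapply(default_profile, function(x) 1)
  default_rates <- list(
    ir_fill = 5, ir_fill_bg = 0.3, benzo_fill = 2,
    oud_dx = 0.02, heroin_dx = 0.002,
    er_visit = 0.5, urgent_visit = 0.3, inpatient_visit = 0.1,
    outpatient_visit = 8,
    pain_dx = 1.5, mh_dx = 0.6, sleep_dx = 0.2, comorbid_dx = 0.4,
    uds = 0.3, sud_treatment = 0.05, surgery = 0.15,
    oud_treatment_prob = 0.03, high_meq_prob = 0.2, early_fill_mean = 1.5)
  cfg <- list(
    n_patients = n_patients,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    latent_prevalence = latent_prevalence,
    effect_profile = utils::modifyList(default_profile, effect_profile),
    neg_profile = utils::modifyList(unit_profile, neg_profile),
    rates = utils::modifyList(default_rates, rates),
    erla_user_frac = erla_user_frac,
    enrollment_gap_hazard = enrollment_gap_hazard,
    onset_delay_mean = onset_delay_mean,
    exclusion_prob = exclusion_prob,
    drug_dictionary = drug_dictionary,
    code_groups = code_groups,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop("invalid sim_config field '", name, "': must be a probability in [0,1]",
           call. = FALSE)
  }
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 0 ||
      cfg$n_patients != round(cfg$n_patients))
    stop("invalid sim_config field 'n_patients': must be a non-negative integer",
         call. = FALSE)
  if (!(cfg$study_start < cfg$study_end))
    stop("invalid sim_config field 'study_period': study_start must precede study_end",
         call. = FALSE)
  chk_prob(cfg$latent_prevalence, "latent_prevalence")
  chk_prob(cfg$erla_user_frac, "erla_user_frac")
  chk_prob(cfg$exclusion_prob, "exclusion_prob")
  for (nm in names(cfg$effect_profile)) {
    x <- cfg$effect_profile[[nm]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
      stop("invalid sim_config field 'effect_profile$", nm,
           "': multipliers must be > 0", call. = FALSE)
  }
  for (nm in names(cfg$neg_profile)) {
    x <- cfg$neg_profile[[nm]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
      stop("invalid sim_config field 'neg_profile$", nm,
           "': multipliers must be >= 0", call. = FALSE)
  }
  for (nm in names(cfg$rates)) {
    x <- cfg$rates[[nm]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
      stop("invalid sim_config field 'rates$", nm, "': must be >= 0",
           call. = FALSE)
  }
  if (cfg$rates$oud_treatment_prob > 1)
    stop("invalid sim_config field 'rates$oud_treatment_prob': probability > 1",
         call. = FALSE)
  if (cfg$enrollment_gap_hazard < 0)
    stop("invalid sim_config field 'enrollment_gap_hazard': must be >= 0",
         call. = FALSE)
  if (cfg$onset_delay_mean <= 0)
    stop("invalid sim_config field 'onset_delay_mean': must be > 0",
         call. = FALSE)
  invisible(cfg)
}

empty_population <- function(config = NULL) {
  d <- as.Date(character(0))
  list(
    demographics = data.frame(patient_id = character(0), birth_date = d,
                              sex = character(0), race = character(0),
                              excluded = logical(0)),
    enrollment = data.frame(patient_id = character(0), start_date = d,
                            end_date = d),
    encounters = data.frame(patient_id = character(0), date = d,
                            setting = character(0)),
    diagnoses = data.frame(patient_id = character(0), date = d,
                           code = character(0), setting = character(0)),
    procedures = data.frame(patient_id = character(0), date = d,
                            category = character(0)),
    dispensings = data.frame(patient_id = character(0), dispense_date = d,
                             drug_code = character(0), drug_class = character(0),
                             days_supply = numeric(0), quantity = numeric(0),
                             mg_per_unit = numeric(0), meq_factor = numeric(0)),
    labels = data.frame(patient_id = character(0), problem_use = logical(0),
                        onset_date = d))
}

#' Generate a synthetic claims population
#'
#' Produces the seven tables of the simplified CDM (demographics, enrollment,
#' encounters, diagnoses, procedures, dispensings, reference-standard labels)
#' as a deterministic function of the configuration and its seed. Each
#' patient's event streams are piecewise-constant-rate Poisson processes
#' within enrollment; trait-positive patients draw from rates multiplied by
#' `config$effect_profile`, and their documented onset date is the latent
#' onset plus a geometric documentation delay.
#'
#' Calling this function seeds and advances R's global random number stream
#' from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list of class `claims_population` with elements `demographics`,
#'   `enrollment`, `encounters`, `diagnoses`, `procedures`, `dispensings`,
#'   `labels`, and the generating `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_patients
  if (n == 0) {
    out <- empty_population(config)
    out$config <- config
    class(out) <- "claims_population"
    return(out)
  }
  set.seed(config$seed)
  span_days <- as.numeric(config$study_end - config$study_start)

  demographics <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    birth_date = config$study_start -
      round(runif(n, 18, 85) * 365.25) - sample.int(365L, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45)),
    race = sample(c("White", "Black", "Native American", "Asian",
                    "Pacific Islander", "Unknown"), n, replace = TRUE,
                  prob = c(0.793, 0.037, 0.035, 0.016, 0.006, 0.113)),
    excluded = runif(n) < config$exclusion_prob,
    stringsAsFactors = FALSE)

  trait <- runif(n) < config$latent_prevalence

  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- generate_patient_streams(trait[i], demographics[i, ], config)
  }
  bind <- function(field) {
    do.call(rbind, c(lapply(streams, `[[`, field), list(make.row.names = FALSE)))
  }
  out <- list(
    demographics = demographics,
    enrollment = bind("enrollment"),
    encounters = bind("encounters"),
    diagnoses = bind("diagnoses"),
    procedures = bind("procedures"),
    dispensings = bind("dispensings"),
    labels = bind("labels"),
    config = config)
  class(out) <- "claims_population"
  out
}

#' @export
print.claims_population <- function(x, ...) {
  cat("<claims_population>", nrow(x$demographics), "patients,",
      nrow(x$dispensings), "dispensings,", nrow(x$diagnoses), "diagnoses,",
      sum(x$labels$problem_use), "reference-positive\n")
  invisible(x)
}

#' Generate the event streams for one patient
#'
#' Draws enrollment spans, an ER/LA dispensing episode, IR/benzodiazepine/
#' psychoactive fills, diagnoses, encounters, procedures, and the
#' reference-standard label for a single patient. Trait-positive patients use
#' `config$effect_profile` multipliers, trait-negative patients
#' `config$neg_profile`. A latent onset time is drawn for *both* groups and
#' anchors the timing of OUD-related streams, so that with unit multipliers
#' the two groups are distributionally identical; only trait-positive
#' patients receive a `problem_use` label and onset date.
#'
#' This function consumes R's current random number stream; callers
#' (normally [generate_population()]) are responsible for seeding it.
#'
#' @param trait logical, latent problem-use trait.
#' @param demographics one-row demographics data.frame for the patient.
#' @param config a [sim_config()].
#' @return list of one-patient tables: `enrollment`, `encounters`,
#'   `diagnoses`, `procedures`, `dispensings`, `labels`.
#' @export
generate_patient_streams <- function(trait, demographics, config) {
  r <- config$rates
  mult <- if (trait) config$effect_profile else config$neg_profile
  pid <- demographics$patient_id
  s0 <- config$study_start
  s1 <- config$study_end
  total <- as.numeric(s1 - s0)

  # --- enrollment: one long span, occasionally split by gaps -------------
  start <- s0 + floor(runif(1, 0, total * 0.25))
  end <- s1 - floor(runif(1, 0, total * 0.15))
  if (as.numeric(end - start) < 730) {
    start <- max(s0, end - 1095)
  }
  years <- as.numeric(end - start) / 365.25
  n_gaps <- rpois(1, config$enrollment_gap_hazard * years)
  spans <- data.frame(start_date = start, end_date = end)
  if (n_gaps > 0) {
    gap_starts <- sort(start + floor(runif(n_gaps, 30, max(31, as.numeric(end - start) - 150))))
    for (g in gap_starts) {
      g <- as.Date(g, origin = "1970-01-01")
      len <- sample(15:120, 1)
      k <- which(spans$start_date < g & spans$end_date > g + len)
      if (length(k) == 1) {
        old_end <- spans$end_date[k]
        spans$end_date[k] <- g - 1
        spans <- rbind(spans, data.frame(start_date = g + len, end_date = old_end))
      }
    }
    spans <- spans[order(spans$start_date), , drop = FALSE]
  }
  enroll_years <- sum(as.numeric(spans$end_date - spans$start_date) + 1) / 365.25

  clamp <- function(d) pmin(pmax(d, s0), s1)
  in_spans <- function(d) {
    keep <- rep(FALSE, length(d))
    for (k in seq_len(nrow(spans)))
      keep <- keep | (d >= spans$start_date[k] & d <= spans$end_date[k])
    keep
  }
  sample_in_spans <- function(nev) {
    if (nev == 0) return(as.Date(character(0)))
    lens <- as.numeric(spans$end_date - spans$start_date) + 1
    k <- sample.int(nrow(spans), nev, replace = TRUE, prob = lens)
    spans$start_date[k] + floor(runif(nev, 0, lens[k]))
  }

  dd <- config$drug_dictionary
  erla <- dd[dd$drug_class == "ERLA_opioid", ]
  ir <- dd[dd$drug_class == "IR_opioid", ]

  # --- ER/LA episode ------------------------------------------------------
  disp <- list()
  episode <- NULL
  if (runif(1) < config$erla_user_frac) {
    lo <- spans$start_date[1] + 180
    hi <- spans$end_date[nrow(spans)] - 545
    if (lo >= hi) { lo <- spans$start_date[1]; hi <- spans$end_date[nrow(spans)] - 90 }
    if (lo < hi) {
      ep_start <- lo + floor(runif(1, 0, as.numeric(hi - lo)))
      ep_len <- min(round(exp(rnorm(1, log(900), 0.7))),
                    as.numeric(spans$end_date[nrow(spans)] - ep_start))
      ep_len <- max(ep_len, 90)
      episode <- c(ep_start, ep_start + ep_len)
      t <- ep_start
      p_high <- min(0.95, r$high_meq_prob * mult$high_meq)
      f_date <- f_supply <- f_drug <- numeric(0)
      while (as.numeric(t - ep_start) <= ep_len && t <= s1) {
        supply <- sample(c(28, 30, 90), 1, prob = c(0.35, 0.55, 0.10))
        pool_idx <- which(erla$high_strength == (runif(1) < p_high))
        f_date <- c(f_date, as.numeric(t))
        f_supply <- c(f_supply, supply)
        f_drug <- c(f_drug, pool_idx[sample.int(length(pool_idx), 1)])
        early <- min(round(rexp(1, 1 / max(r$early_fill_mean * mult$early_fill, 1e-9))),
                     supply - 7)
        t <- t + supply - max(early, 0)
      }
      if (length(f_date) > 0) {
        upd <- sample(1:3, length(f_date), replace = TRUE)
        disp[[length(disp) + 1]] <- data.frame(
          patient_id = pid,
          dispense_date = as.Date(f_date, origin = "1970-01-01"),
          drug_code = erla$drug_code[f_drug],
          drug_class = "ERLA_opioid", days_supply = f_supply,
          quantity = f_supply * upd, mg_per_unit = erla$mg_per_unit[f_drug],
          meq_factor = erla$meq_factor[f_drug], stringsAsFactors = FALSE)
      }
    }
  }

  # --- IR fills -----------------------------------------------------------
  ir_dates <- as.Date(character(0))
  if (!is.null(episode)) {
    ep_years <- as.numeric(episode[2] - episode[1]) / 365.25
    n_ir <- rpois(1, r$ir_fill * mult$early_fill * ep_years)
    ir_dates <- episode[1] + floor(runif(n_ir, 0, as.numeric(episode[2] - episode[1]) + 1))
  }
  n_bg <- rpois(1, r$ir_fill_bg * enroll_years)
  ir_dates <- clamp(c(ir_dates, sample_in_spans(n_bg)))
  if (length(ir_dates) > 0) {
    k <- sample.int(nrow(ir), length(ir_dates), replace = TRUE)
    supply <- sample(c(5, 7, 10, 14, 30), length(ir_dates), replace = TRUE,
                     prob = c(0.2, 0.25, 0.25, 0.2, 0.1))
    disp[[length(disp) + 1]] <- data.frame(
      patient_id = pid, dispense_date = ir_dates, drug_code = ir$drug_code[k],
      drug_class = "IR_opioid", days_supply = supply, quantity = supply * 3,
      mg_per_unit = ir$mg_per_unit[k], meq_factor = ir$meq_factor[k],
      stringsAsFactors = FALSE)
  }

  # --- benzodiazepines / other psychoactives ------------------------------
  n_bzd <- rpois(1, r$benzo_fill * mult$benzo * enroll_years)
  if (n_bzd > 0) {
    pool <- dd[dd$drug_class %in% c("benzodiazepine", "other_psychoactive"), ]
    k <- sample.int(nrow(pool), n_bzd, replace = TRUE)
    disp[[length(disp) + 1]] <- data.frame(
      patient_id = pid, dispense_date = clamp(sample_in_spans(n_bzd)),
      drug_code = pool$drug_code[k], drug_class = pool$drug_class[k],
      days_supply = 30, quantity = 30, mg_per_unit = pool$mg_per_unit[k],
      meq_factor = NA_real_, stringsAsFactors = FALSE)
  }

  # --- latent onset (drawn for both groups; labels only for positives) ----
  anchor <- if (!is.null(episode)) episode[1] else sample_in_spans(1)
  latent_onset <- clamp(anchor + round(runif(1, -180, 365)))

  # --- OUD-treatment medication -------------------------------------------
  p_tx <- min(1, r$oud_treatment_prob * mult$oud_treatment)
  if (runif(1) < p_tx) {
    tx_start <- clamp(latent_onset + sample.int(180L, 1))
    n_tx <- sample.int(6L, 1)
    oud_drugs <- dd[dd$drug_class == "OUD_treatment", ]
    drug <- oud_drugs[sample.int(nrow(oud_drugs), 1), ]
    dates <- clamp(tx_start + (seq_len(n_tx) - 1) * 28)
    disp[[length(disp) + 1]] <- data.frame(
      patient_id = pid, dispense_date = dates, drug_code = drug$drug_code,
      drug_class = "OUD_treatment", days_supply = 28, quantity = 28,
      mg_per_unit = drug$mg_per_unit, meq_factor = NA_real_,
      stringsAsFactors = FALSE)
  }

  dispensings <- if (length(disp)) do.call(rbind, disp) else empty_population()$dispensings
  dispensings <- dispensings[dispensings$dispense_date >= s0 &
                               dispensings$dispense_date <= s1, , drop = FALSE]

  # --- diagnoses ----------------------------------------------------------
  cg <- config$code_groups
  pick_code <- function(groups, nev) {
    prefixes <- unlist(cg[groups], use.names = FALSE)
    p <- prefixes[sample.int(length(prefixes), nev, replace = TRUE)]
    ifelse(endsWith(p, "."), paste0(p, sprintf("%02d", sample(0:9, nev, replace = TRUE))), p)
  }
  dx <- list()
  add_dx <- function(rate_py, groups, from = NULL, to = NULL) {
    if (is.null(from)) {
      nev <- rpois(1, rate_py * enroll_years)
      dates <- sample_in_spans(nev)
    } else {
      yrs <- max(as.numeric(to - from), 0) / 365.25
      nev <- rpois(1, rate_py * yrs)
      dates <- if (nev > 0) from + floor(runif(nev, 0, max(as.numeric(to - from), 1))) else as.Date(character(0))
      dates <- dates[in_spans(dates)]
      nev <- length(dates)
    }
    if (nev == 0) return(invisible(NULL))
    dx[[length(dx) + 1]] <<- data.frame(
      patient_id = pid, date = clamp(dates), code = pick_code(groups, nev),
      setting = sample(c("outpatient", "ER", "inpatient"), nev, replace = TRUE,
                       prob = c(0.8, 0.15, 0.05)),
      stringsAsFactors = FALSE)
  }
  add_dx(r$pain_dx, c("pain_back", "pain_neck", "headache", "neuropathic_pain",
                      "fibromyalgia", "arthritis"))
  add_dx(r$mh_dx, c("depression", "anxiety", "bipolar", "other_mental_health", "ptsd"))
  add_dx(r$sleep_dx, "sleep_disorder")
  add_dx(r$comorbid_dx, grep("^charlson_", names(cg), value = TRUE))
  add_dx(r$comorbid_dx / 4, c("alcohol_disorder", "tobacco", "nondependent_abuse"))
  # OUD diagnoses: elevated hazard applies after the latent onset
  add_dx(r$oud_dx * mult$oud_dx,
         c("opioid_dependence", "opioid_abuse", "opioid_poisoning"),
         from = latent_onset, to = spans$end_date[nrow(spans)])
  add_dx(r$heroin_dx, "heroin")
  diagnoses <- if (length(dx)) do.call(rbind, dx) else empty_population()$diagnoses

  # --- encounters ---------------------------------------------------------
  enc <- list()
  add_enc <- function(rate_py, setting, m = 1) {
    nev <- rpois(1, rate_py * m * enroll_years)
    if (nev == 0) return(invisible(NULL))
    enc[[length(enc) + 1]] <<- data.frame(
      patient_id = pid, date = sample_in_spans(nev), setting = setting,
      stringsAsFactors = FALSE)
  }
  add_enc(r$outpatient_visit, "outpatient")
  add_enc(r$er_visit, "ER", mult$er_visit)
  add_enc(r$urgent_visit, "urgent")
  add_enc(r$inpatient_visit, "inpatient")
  encounters <- if (length(enc)) do.call(rbind, enc) else empty_population()$encounters

  # --- procedures (trait-neutral) -----------------------------------------
  pr <- list()
  add_proc <- function(rate_py, category) {
    nev <- rpois(1, rate_py * enroll_years)
    if (nev == 0) return(invisible(NULL))
    pr[[length(pr) + 1]] <<- data.frame(
      patient_id = pid, date = sample_in_spans(nev), category = category,
      stringsAsFactors = FALSE)
  }
  add_proc(r$uds, "urine_drug_screen")
  add_proc(r$sud_treatment, "SUD_treatment")
  add_proc(r$surgery, "surgery")
  procedures <- if (length(pr)) do.call(rbind, pr) else empty_population()$procedures

  # --- reference-standard label ------------------------------------------
  if (trait) {
    delay <- rgeom(1, 1 / config$onset_delay_mean)
    onset <- clamp(latent_onset + delay)
    labels <- data.frame(patient_id = pid, problem_use = TRUE,
                         onset_date = onset, stringsAsFactors = FALSE)
  } else {
    labels <- data.frame(patient_id = pid, problem_use = FALSE,
                         onset_date = as.Date(NA), stringsAsFactors = FALSE)
  }

  list(enrollment = data.frame(patient_id = pid, spans,
                               stringsAsFactors = FALSE),
       encounters = encounters, diagnoses = diagnoses,
       procedures = procedures, dispensings = dispensings, labels = labels)
}

#' Write / read a population as CSV tables
#'
#' Serializes the seven tables as headed CSV files with ISO-8601 dates, the
#' delimited-text interchange format of the pipeline.
#'
#' @param population a `claims_population`.
#' @param dir directory to write into (created if needed).
#' @return `write_population` returns `dir` invisibly; `read_population`
#'   returns a `claims_population` (without the generating config).
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "claims_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tbl in c("demographics", "enrollment", "encounters", "diagnoses",
                "procedures", "dispensings", "labels")) {
    utils::write.csv(population[[tbl]], file.path(dir, paste0(tbl, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  date_cols <- list(demographics = "birth_date",
                    enrollment = c("start_date", "end_date"),
                    encounters = "date", diagnoses = "date",
                    procedures = "date", dispensings = "dispense_date",
                    labels = "onset_date")
  out <- list()
  for (tbl in names(date_cols)) {
    df <- utils::read.csv(file.path(dir, paste0(tbl, ".csv")),
                          stringsAsFactors = FALSE)
    for (cl in date_cols[[tbl]]) df[[cl]] <- as.Date(df[[cl]])
    out[[tbl]] <- df
  }
  class(out) <- "claims_population"
  out
}
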