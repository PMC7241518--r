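#' Define a candidate predictor
#'
#' A predictor spec names a builder family and its parameters; the builder
#' operationalizes the predictor from a patient's claims streams restricted
#' to their 36-month observation window. Families cover the candidate
#' variable categories of the development study: diagnosis flags/counts/
#' percent-of-quarters, days'-supply aggregates, morphine-equivalent dose
#' (MEQ) measures, overlapping-fill ("early fill") patterns, concomitant
#' opioid/psychoactive use, ER encounters during exposure periods,
#' procedure counts and proximity measures, OUD-treatment medications, a
#' simplified Charlson comorbidity index, demographics, and age-group
#' interaction terms.
#'
#' @param name unique predictor name.
#' @param family one of `"diagnosis_flag"`, `"diagnosis_count"`,
#'   `"pct_quarters"`, `"pain_site_count"`, `"days_supply_agg"`,
#'   `"meq_measure"`, `"overlap_fills"`, `"concomitant_use"`,
#'   `"er_during_exposure"`, `"procedure_proximity"`, `"oud_treatment_med"`,
#'   `"charlson"`, `"demographic"`, `"interaction"`.
#' @param params named list of family parameters (see the builder
#'   documentation in the vignette).
#' @param output declared output type: `"binary"`, `"count"`,
#'   `"proportion"`, or `"continuous"`.
#' @return object of class `predictor_spec`.
#' @export
predictor_spec <- function(name, family, params = list(),
                           output = c("binary", "count", "proportion",
                                      "continuous")) {
  output <- match.arg(output)
  families <- c("diagnosis_flag", "diagnosis_count", "pct_quarters",
                "pain_site_count", "days_supply_agg", "meq_measure",
                "overlap_fills", "concomitant_use", "er_during_exposure",
                "procedure_proximity", "oud_treatment_med", "charlson",
                "demographic", "interaction")
  if (!family %in% families)
    stop("predictor_spec: unknown builder family '", family, "'",
         call. = FALSE)
  structure(list(name = name, family = family, params = params,
                 output = output),
            class = "predictor_spec")
}

# --- per-patient evaluation context --------------------------------------

# The context caches window-restricted tables and lazily computed day-level
# series (MEQ, coverage masks) shared by many builders.
build_patient_context <- function(member, demo_row, disp, dx, enc, proc) {
  ctx <- new.env(parent = emptyenv())
  ctx$window <- c(member$observation_start, member$observation_end)
  ctx$ndays <- as.integer(ctx$window[2] - ctx$window[1]) + 1L
  ctx$index_date <- member$index_date
  ctx$demo <- demo_row
  ctx$disp <- disp[disp$dispense_date >= ctx$window[1] &
                     disp$dispense_date <= ctx$window[2], , drop = FALSE]
  ctx$dx <- dx[dx$date >= ctx$window[1] & dx$date <= ctx$window[2], , drop = FALSE]
  ctx$enc <- enc[enc$date >= ctx$window[1] & enc$date <= ctx$window[2], , drop = FALSE]
  ctx$proc <- proc[proc$date >= ctx$window[1] & proc$date <= ctx$window[2], , drop = FALSE]
  ctx$quarters <- quarters_in_window(ctx$window[1], ctx$window[2])
  lt1 <- as.POSIXlt(ctx$window[1]); lt2 <- as.POSIXlt(ctx$window[2])
  ctx$nmonths <- (lt2$year * 12L + lt2$mon) - (lt1$year * 12L + lt1$mon) + 1L
  ctx
}

ctx_meq <- function(ctx) {
  if (is.null(ctx$meq)) ctx$meq <- daily_meq_series(ctx$disp, ctx$window)
  ctx$meq
}

ctx_day_quarters <- function(ctx) {
  if (is.null(ctx$day_quarters))
    ctx$day_quarters <- quarter_id(seq(ctx$window[1], ctx$window[2], by = "day"))
  ctx$day_quarters
}

ctx_coverage <- function(ctx, key, classes, min_overlap = 1) {
  if (is.null(ctx$cov)) ctx$cov <- list()
  if (is.null(ctx$cov[[key]]))
    ctx$cov[[key]] <- coverage_days(ctx$disp, ctx$window, classes, min_overlap)
  ctx$cov[[key]]
}

dx_quarters_with <- function(ctx, codes) {
  hit <- code_matches(ctx$dx$code, codes)
  unique(quarter_id(ctx$dx$date[hit]))
}

# --- builder dispatch -----------------------------------------------------

build_predictor_value <- function(spec, ctx) {
  p <- spec$params
  switch(spec$family,
    diagnosis_flag = as.numeric(any(code_matches(ctx$dx$code, p$codes))),
    diagnosis_count = {
      n <- sum(code_matches(ctx$dx$code, p$codes))
      grain <- if (is.null(p$grain)) "overall" else p$grain
      switch(grain, overall = n, month = n / ctx$nmonths,
             quarter = n / length(ctx$quarters))
    },
    pct_quarters = length(dx_quarters_with(ctx, p$codes)) / length(ctx$quarters),
    pain_site_count = sum(vapply(p$groups, function(g)
      any(code_matches(ctx$dx$code, g)), logical(1))),
    days_supply_agg = {
      sel <- ctx$disp[ctx$disp$drug_class %in% p$classes, , drop = FALSE]
      stat <- if (is.null(p$stat)) "total" else p$stat
      if (stat == "total") {
        grain <- if (is.null(p$grain)) "overall" else p$grain
        tot <- sum(sel$days_supply)
        switch(grain, overall = tot, month = tot / ctx$nmonths,
               quarter = tot / length(ctx$quarters))
      } else {
        # excess days' supply per calendar quarter
        qs <- quarter_id(sel$dispense_date)
        per_q <- tapply(sel$days_supply, factor(qs, levels = ctx$quarters), sum,
                        default = 0)
        n_excess <- sum(per_q > p$threshold, na.rm = TRUE)
        if (stat == "excess_flag") as.numeric(n_excess > 0) else n_excess
      }
    },
    meq_measure = {
      meq <- ctx_meq(ctx)
      switch(p$stat,
        mean_daily = mean(meq),
        per_supply_day = {
          op <- ctx$disp[ctx$disp$drug_class %in% c("ERLA_opioid", "IR_opioid"), ,
                         drop = FALSE]
          tot_supply <- sum(op$days_supply)
          if (tot_supply == 0) 0 else sum(meq) / tot_supply
        },
        max_daily = max(meq, 0),
        days_ge = sum(meq >= p$threshold),
        pct_quarters_ge = {
          qmeans <- tapply(meq, factor(ctx_day_quarters(ctx), levels = ctx$quarters),
                           mean, default = 0)
          mean(qmeans >= p$threshold, na.rm = TRUE)
        },
        change_ge = {
          qmeans <- as.numeric(tapply(meq,
            factor(ctx_day_quarters(ctx), levels = ctx$quarters), mean,
            default = 0))
          if (length(qmeans) < 2) return(0)
          prev <- head(qmeans, -1); nxt <- tail(qmeans, -1)
          as.numeric(any(prev > 0 & nxt >= (1 + p$frac) * prev))
        },
        stop("meq_measure: unknown stat '", p$stat, "'", call. = FALSE))
    },
    overlap_fills = {
      res <- detect_overlap_events(
        ctx$disp,
        class_filter = if (is.null(p$class_filter)) "IR_opioid" else p$class_filter,
        max_days_supply = if (is.null(p$max_days_supply)) 14 else p$max_days_supply,
        dow_set = p$dow_set,
        window_len_months = if (is.null(p$window_len_months)) 3 else p$window_len_months,
        min_fills = if (is.null(p$min_fills)) 3 else p$min_fills,
        value = if (is.null(p$value)) "flag" else p$value)
      as.numeric(res)
    },
    concomitant_use = {
      op <- ctx_coverage(ctx, "opioid", c("ERLA_opioid", "IR_opioid"))
      ps <- ctx_coverage(ctx, "psycho", c("benzodiazepine", "other_psychoactive"))
      both <- op & ps
      switch(p$stat,
        days = sum(both),
        flag = as.numeric(any(both)),
        pct_quarters = {
          qs <- unique(ctx_day_quarters(ctx)[both])
          length(qs) / length(ctx$quarters)
        },
        stop("concomitant_use: unknown stat '", p$stat, "'", call. = FALSE))
    },
    er_during_exposure = {
      er_days <- as.integer(ctx$enc$date[ctx$enc$setting == "ER"] - ctx$window[1]) + 1L
      cond <- switch(p$condition,
        any = rep(TRUE, ctx$ndays),
        opioid_coverage = ctx_coverage(ctx, "opioid", c("ERLA_opioid", "IR_opioid")),
        overlap = ctx_coverage(ctx, "opioid2", c("ERLA_opioid", "IR_opioid"),
                               min_overlap = 2),
        high_meq = ctx_meq(ctx) >= p$threshold,
        stop("er_during_exposure: unknown condition '", p$condition, "'",
             call. = FALSE))
      n <- sum(cond[er_days])
      if (!is.null(p$value) && p$value == "flag") as.numeric(n > 0) else n
    },
    procedure_proximity = {
      sel <- ctx$proc[ctx$proc$category == p$category, , drop = FALSE]
      stat <- if (is.null(p$stat)) "count" else p$stat
      if (stat == "count") return(nrow(sel))
      if (stat == "flag") return(as.numeric(nrow(sel) > 0))
      if (stat == "pct_quarters") {
        qs <- unique(quarter_id(sel$date))
        return(length(qs) / length(ctx$quarters))
      }
      qual <- switch(stat,
        near_overlap = ctx_coverage(ctx, "opioid2", c("ERLA_opioid", "IR_opioid"),
                                    min_overlap = 2),
        near_high_meq = ctx_meq(ctx) >= p$threshold,
        stop("procedure_proximity: unknown stat '", stat, "'", call. = FALSE))
      qdays <- which(qual)
      if (length(qdays) == 0 || nrow(sel) == 0) return(0)
      pdays <- as.integer(sel$date - ctx$window[1]) + 1L
      k <- if (is.null(p$k)) 7 else p$k
      sum(vapply(pdays, function(d) any(abs(qdays - d) <= k), logical(1)))
    },
    oud_treatment_med = {
      sel <- ctx$disp[ctx$disp$drug_class == "OUD_treatment", , drop = FALSE]
      switch(p$stat,
        ever = as.numeric(nrow(sel) > 0),
        days_supply = sum(sel$days_supply),
        stop("oud_treatment_med: unknown stat '", p$stat, "'", call. = FALSE))
    },
    charlson = {
      w <- charlson_weights()
      groups <- p$code_groups
      sum(vapply(names(w), function(g)
        if (any(code_matches(ctx$dx$code, groups[[g]]))) w[[g]] else 0,
        numeric(1)))
    },
    demographic = {
      age <- age_at(ctx$demo$birth_date, ctx$index_date)
      switch(p$var,
        age = age,
        age_18_34 = as.numeric(age < 35),
        age_ge_65 = as.numeric(age >= 65),
        sex_female = as.numeric(ctx$demo$sex == "F"),
        stop("demographic: unknown var '", p$var, "'", call. = FALSE))
    },
    interaction = {
      age <- age_at(ctx$demo$birth_date, ctx$index_date)
      ind <- switch(p$age_group,
        "18-34" = as.numeric(age < 35),
        "35+" = as.numeric(age >= 35),
        "65+" = as.numeric(age >= 65),
        stop("interaction: unknown age_group '", p$age_group, "'",
             call. = FALSE))
      ind * build_predictor_value(p$base, ctx)
    },
    stop("build_predictor: unknown family '", spec$family, "'", call. = FALSE))
}

#' Evaluate one predictor for one cohort member
#'
#' Restricts the patient's claims streams to the member's observation window
#' and dispatches to the spec's builder family.
#'
#' @param population a `claims_population` (or compatible list of tables).
#' @param spec a [predictor_spec()].
#' @param member one row of the cohort data.frame from [build_cohort()].
#' @return a single numeric value.
#' @export
build_predictor <- function(population, spec, member) {
  stopifnot(inherits(spec, "predictor_spec"), nrow(member) == 1)
  pid <- member$patient_id
  demo <- population$demographics[population$demographics$patient_id == pid, ,
                                  drop = FALSE]
  sub <- function(tbl) tbl[tbl$patient_id == pid, , drop = FALSE]
  ctx <- build_patient_context(member, demo, sub(population$dispensings),
                               sub(population$diagnoses),
                               sub(population$encounters),
                               sub(population$procedures))
  build_predictor_value(spec, ctx)
}

#' Build the patients-by-predictors matrix
#'
#' Evaluates a spec library for every cohort member over their observation
#' windows. Absence of events encodes as 0 (no missing cells), binary
#' predictors are 0/1, and the result is invariant to the order of records
#' in the input tables.
#'
#' @param population a `claims_population`.
#' @param cohort cohort data.frame from [build_cohort()].
#' @param specs list of [predictor_spec()]s with unique names (default: the
#'   shipped library, [default_predictor_library()]).
#' @return numeric matrix (rownames = patient ids, colnames = predictor
#'   names) with the spec list attached as attribute `"specs"` for
#'   provenance.
#' @export
build_matrix <- function(population, cohort,
                         specs = default_predictor_library()) {
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("build_matrix: duplicate predictor names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  ids <- cohort$patient_id
  out <- matrix(0, nrow = length(ids), ncol = length(specs),
                dimnames = list(ids, nms))
  if (length(ids) > 0) {
    disp_by <- split_by_patient(population$dispensings, ids)
    dx_by <- split_by_patient(population$diagnoses, ids)
    enc_by <- split_by_patient(population$encounters, ids)
    proc_by <- split_by_patient(population$procedures, ids)
    demo_idx <- match(ids, population$demographics$patient_id)
    for (i in seq_along(ids)) {
      pid <- ids[i]
      ctx <- build_patient_context(cohort[i, ],
                                   population$demographics[demo_idx[i], ],
                                   disp_by[[pid]], dx_by[[pid]],
                                   enc_by[[pid]], proc_by[[pid]])
      for (j in seq_along(specs))
        out[i, j] <- build_predictor_value(specs[[j]], ctx)
    }
  }
  out[is.na(out)] <- 0
  attr(out, "specs") <- specs
  out
}

#' Risk-ratio screen for candidate predictors
#'
#' For each predictor, computes the percentage of reference-standard
#' positives with the (dichotomized) predictor TRUE, the percentage of
#' negatives with it TRUE, and their ratio
#' `RR = pct_true_positives / pct_true_negatives`. Predictors with larger RR
#' and more predictor-positive patients carry more discriminating signal.
#' Non-binary predictors are dichotomized first: at a configured cut-point
#' (`value >= cut`) when provided, otherwise at `value > 0`.
#'
#' @param X predictor matrix from [build_matrix()].
#' @param outcomes logical reference-standard outcome, aligned with rows.
#' @param dichotomization_rules optional named numeric vector/list of
#'   cut-points per predictor.
#' @return data.frame `predictor`, `pct_true_positives`,
#'   `pct_true_negatives`, `rr`, `n_true`, `undefined` (TRUE when no
#'   negative has the predictor, where RR would divide by zero).
#' @export
risk_ratio_screen <- function(X, outcomes, dichotomization_rules = NULL) {
  stopifnot(nrow(X) == length(outcomes))
  outcomes <- as.logical(outcomes)
  res <- lapply(colnames(X), function(nm) {
    x <- X[, nm]
    cut <- dichotomization_rules[[nm]]
    b <- if (!is.null(cut)) x >= cut else
      if (all(x %in% c(0, 1))) x == 1 else x > 0
    pct_pos <- 100 * mean(b[outcomes])
    pct_neg <- 100 * mean(b[!outcomes])
    undef <- pct_neg == 0
    data.frame(predictor = nm,
               pct_true_positives = pct_pos,
               pct_true_negatives = pct_neg,
               rr = if (undef) NA_real_ else pct_pos / pct_neg,
               n_true = sum(b), undefined = undef,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
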