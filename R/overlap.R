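#' Detect chains of partially overlapping dispensings ("early fills")
#'
#' A fill *partially overlaps* another when its dispense date falls on or
#' before the other fill's coverage end (`dispense_date + days_supply - 1`).
#' The detector searches for a chain of at least `min_fills` qualifying fills
#' — each passing the drug-class, maximum-days'-supply and day-of-week
#' filters, and each overlapping another qualifying fill of the chain —
#' occurring within some rolling span of `window_len_months` calendar
#' months. Chains are connected components of the pairwise overlap graph
#' among qualifying fills inside the span (spans are anchored at each
#' qualifying fill's dispense date).
#'
#' The canonical instance flags patients with >= 3 partially overlapping IR
#' dispensings of <= 14 days' supply filled on a Saturday, Sunday or Monday
#' within a 3-month period.
#'
#' @param dispensings dispensing records (one patient).
#' @param class_filter drug classes to consider (default `"IR_opioid"`).
#' @param max_days_supply only fills with `days_supply` at or below this
#'   qualify (default 14; `Inf` disables).
#' @param dow_set day-of-week filter as English abbreviations
#'   (default `c("Sat", "Sun", "Mon")`; `NULL` disables).
#' @param window_len_months rolling span length in calendar months.
#' @param min_fills chain size required to flag (default 3).
#' @param value `"flag"` (default) returns TRUE/FALSE; `"count"` returns the
#'   largest chain size found in any span (0 when no qualifying fills).
#' @return logical or integer scalar.
#' @export
detect_overlap_events <- function(dispensings, class_filter = "IR_opioid",
                                  max_days_supply = 14,
                                  dow_set = c("Sat", "Sun", "Mon"),
                                  window_len_months = 3, min_fills = 3,
                                  value = c("flag", "count")) {
  value <- match.arg(value)
  stopifnot(all(class_filter %in% c("ERLA_opioid", "IR_opioid", "benzodiazepine",
                                    "other_psychoactive", "OUD_treatment", "other")))
  q <- dispensings[dispensings$drug_class %in% class_filter &
                     dispensings$days_supply <= max_days_supply, , drop = FALSE]
  if (!is.null(dow_set)) {
    dow <- weekdays_abbrev(q$dispense_date)
    q <- q[dow %in% dow_set, , drop = FALSE]
  }
  best <- 0L
  if (nrow(q) >= 2) {
    q <- q[order(q$dispense_date, q$days_supply), , drop = FALSE]
    d <- q$dispense_date
    cov_end <- d + q$days_supply - 1
    for (i in seq_along(d)) {
      span_end <- add_months(d[i], window_len_months) - 1
      in_span <- which(d >= d[i] & d <= span_end)
      if (length(in_span) <= best) next
      best <- max(best, max_overlap_component(d[in_span], cov_end[in_span]))
    }
  } else if (nrow(q) == 1) {
    best <- 1L
  }
  if (value == "flag") best >= min_fills else as.integer(best)
}

# Size of the largest connected component of the interval-overlap graph.
max_overlap_component <- function(starts, ends) {
  m <- length(starts)
  if (m == 0) return(0L)
  comp <- seq_len(m)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (starts[j] <= ends[i] && starts[i] <= ends[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  max(tabulate(roots))
}

# Locale-independent weekday abbreviations.
weekdays_abbrev <- function(dates) {
  c("Thu", "Fri", "Sat", "Sun", "Mon", "Tue", "Wed")[
    (as.integer(dates) %% 7L) + 1L]
}
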