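#' Daily morphine-equivalent dose series
#'
#' Expands opioid dispensings into a per-day morphine-equivalent (MEQ) dose
#' series over a window. Each fill covers the closed interval
#' `[dispense_date, dispense_date + days_supply - 1]` and contributes
#' `quantity * mg_per_unit * meq_factor / days_supply` MEQ on each covered
#' day; overlapping fills add. Days with no coverage are 0.
#'
#' @param dispensings dispensing records; only rows of class `ERLA_opioid` or
#'   `IR_opioid` are used (these must carry `meq_factor`).
#' @param window `c(start, end)` Dates, the closed evaluation window.
#' @return numeric vector of length `window[2] - window[1] + 1` (one entry
#'   per day), with attribute `start` = `window[1]`.
#' @export
daily_meq_series <- function(dispensings, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  op <- dispensings[dispensings$drug_class %in% c("ERLA_opioid", "IR_opioid"), ,
                    drop = FALSE]
  if (any(op$days_supply <= 0))
    stop("daily_meq_series: days_supply must be >= 1", call. = FALSE)
  if (any(is.na(op$meq_factor)))
    stop("daily_meq_series: opioid dispensing without meq_factor", call. = FALSE)
  ndays <- as.integer(window[2] - window[1]) + 1L
  out <- numeric(ndays)
  if (nrow(op) > 0) {
    daily <- op$quantity * op$mg_per_unit * op$meq_factor / op$days_supply
    from <- as.integer(op$dispense_date - window[1]) + 1L
    to <- from + as.integer(op$days_supply) - 1L
    for (k in seq_len(nrow(op))) {
      i <- max(from[k], 1L)
      j <- min(to[k], ndays)
      if (i <= j) out[i:j] <- out[i:j] + daily[k]
    }
  }
  attr(out, "start") <- window[1]
  out
}

# Logical coverage vector over the window days for fills of the given
# classes; `min_overlap` asks for days covered by at least that many fills.
coverage_days <- function(dispensings, window, classes, min_overlap = 1) {
  sel <- dispensings[dispensings$drug_class %in% classes, , drop = FALSE]
  ndays <- as.integer(window[2] - window[1]) + 1L
  cnt <- integer(ndays)
  if (nrow(sel) > 0) {
    from <- as.integer(sel$dispense_date - window[1]) + 1L
    to <- from + as.integer(sel$days_supply) - 1L
    for (k in seq_len(nrow(sel))) {
      i <- max(from[k], 1L)
      j <- min(to[k], ndays)
      if (i <= j) cnt[i:j] <- cnt[i:j] + 1L
    }
  }
  cnt >= min_overlap
}
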