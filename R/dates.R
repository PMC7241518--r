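# Calendar arithmetic used throughout cohort construction and predictor
# windows. All month offsets clamp to the end of the target month
# (e.g. 2010-01-31 + 1 month -> 2010-02-28).

#' Shift dates by calendar months with end-of-month clamping
#'
#' @param date a `Date` vector.
#' @param n integer number of months (may be negative, scalar or vectorized).
#' @return a `Date` vector.
#' @examples
#' add_months(as.Date("2010-01-31"), 1)  # 2010-02-28
#' add_months(as.Date("2010-06-01"), -6) # 2009-12-01
#' @export
add_months <- function(date, n) {
  stopifnot(inherits(date, "Date"))
  lt <- as.POSIXlt(date)
  m0 <- lt$year * 12L + lt$mon + as.integer(n)
  year <- m0 %/% 12L + 1900L
  month <- m0 %% 12L + 1L
  day <- pmin(lt$mday, days_in_month(year, month))
  out <- as.Date(rep(NA_integer_, length(m0)), origin = "1970-01-01")
  ok <- !is.na(m0) & !is.na(day)
  if (any(ok))
    out[ok] <- as.Date(sprintf("%04d-%02d-%02d", year[ok], month[ok], day[ok]))
  out
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  ifelse(month == 2L & leap, 29L, base)
}

#' Calendar quarter identifiers
#'
#' @param date a `Date` vector.
#' @return character vector like `"2010Q3"`; `NA` dates give `NA`.
#' @export
quarter_id <- function(date) {
  stopifnot(inherits(date, "Date"))
  lt <- as.POSIXlt(date)
  out <- sprintf("%04dQ%d", lt$year + 1900L, lt$mon %/% 3L + 1L)
  out[is.na(date)] <- NA_character_
  out
}

# Sequence of quarter ids intersecting the closed interval [start, end].
quarters_in_window <- function(start, end) {
  stopifnot(start <= end)
  firsts <- seq(quarter_start(start), end, by = "3 months")
  quarter_id(firsts)
}

quarter_start <- function(date) {
  lt <- as.POSIXlt(date)
  as.Date(sprintf("%04d-%02d-01", lt$year + 1900L, (lt$mon %/% 3L) * 3L + 1L))
}

# Age in completed years at `at` for someone born `birth`.
age_at <- function(birth, at) {
  by <- as.POSIXlt(birth)
  ay <- as.POSIXlt(at)
  age <- ay$year - by$year
  before_bday <- (ay$mon < by$mon) | (ay$mon == by$mon & ay$mday < by$mday)
  age - as.integer(before_bday)
}
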