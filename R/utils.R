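#' Age in completed years at a given date
#'
#' Calendar age as used for the per-measurement serum-creatinine conversion:
#' the number of whole birthdays elapsed between `birth_date` and `date`.
#'
#' @param birth_date,date `Date` vectors (recycled to common length).
#' @return Integer vector of completed years.
#' @export
age_completed_years <- function(birth_date, date) {
  age_from_ints(day_int(birth_date), day_int(date))
}

# civil calendar fields from days-since-epoch (proleptic Gregorian),
# integer arithmetic only — far cheaper than as.POSIXlt in tight loops
civil_from_days <- function(z) {
  z <- z + 719468
  era <- z %/% 146097
  doe <- z - era * 146097
  yoe <- (doe - doe %/% 1460 + doe %/% 36524 - doe %/% 146096) %/% 365
  y <- yoe + era * 400
  doy <- doe - (365 * yoe + yoe %/% 4 - yoe %/% 100)
  mp <- (5 * doy + 2) %/% 153
  d <- doy - (153 * mp + 2) %/% 5 + 1
  m <- mp + ifelse(mp < 10, 3, -9)
  list(year = y + (m <= 2), month = m, day = d)
}

age_from_ints <- function(birth_i, date_i) {
  b <- civil_from_days(as.numeric(birth_i))
  d <- civil_from_days(as.numeric(date_i))
  as.integer(d$year - b$year -
               ((d$month < b$month) |
                  (d$month == b$month & d$day < b$day)))
}

# Date -> integer days since 1970-01-01 (dates are day-resolution throughout)
day_int <- function(d) as.integer(unclass(as.Date(d)))

int_day <- function(i) structure(as.numeric(i), class = "Date")

`%||%` <- function(a, b) if (is.null(a)) b else a
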