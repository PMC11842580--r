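#' Dekad (10-day period) calendar
#'
#' The CDI's temporal unit is the dekad: each calendar month is split into
#' three periods, days 1-10, days 11-20, and day 21 through the month end.
#' There are therefore exactly 36 dekads per year, and the third dekad of a
#' month spans 8, 9, 10 or 11 days depending on the month. Dekads are
#' numbered 1..36 within a year via `ordinal = 3 * (month - 1) +
#' dekad_of_month`, so that file names and time axes are unambiguous.
#'
#' @param year Calendar year (integer, >= 1).
#' @param ordinal Dekad of the year, 1..36. Alternatively supply `month`
#'   and `dekad_of_month`.
#' @param month Month 1..12 (used when `ordinal` is missing).
#' @param dekad_of_month Dekad within the month, 1..3.
#'
#' @return An object of class `"dekad"` with fields `year`, `ordinal`,
#'   `month` and `dekad_of_month`.
#' @examples
#' dekad(2020, 5)                      # second dekad of February 2020
#' dekad(2020, month = 2, dekad_of_month = 2)
#' @export
dekad <- function(year, ordinal = NULL, month = NULL, dekad_of_month = NULL) {
  if (is.null(ordinal)) {
    stopifnot(!is.null(month), !is.null(dekad_of_month))
    ordinal <- 3L * (as.integer(month) - 1L) + as.integer(dekad_of_month)
  }
  year <- as.integer(year)
  ordinal <- as.integer(ordinal)
  stopifnot(length(year) == 1L, length(ordinal) == 1L,
            year >= 1L, ordinal >= 1L, ordinal <= 36L)
  structure(
    list(year = year, ordinal = ordinal,
         month = (ordinal - 1L) %/% 3L + 1L,
         dekad_of_month = (ordinal - 1L) %% 3L + 1L),
    class = "dekad"
  )
}

#' @export
format.dekad <- function(x, ...) {
  sprintf("%04d-%02d d%d", x$year, x$month, x$dekad_of_month)
}

#' @export
print.dekad <- function(x, ...) {
  cat("<dekad>", format(x), sprintf("(ordinal %d)", x$ordinal), "\n")
  invisible(x)
}

#' @export
`==.dekad` <- function(e1, e2) {
  e1$year == e2$year && e1$ordinal == e2$ordinal
}

days_in_month <- function(year, month) {
  # last day of month via first day of next month minus one
  first_next <- if (month == 12L) as.Date(sprintf("%04d-01-01", year + 1L)) else
    as.Date(sprintf("%04d-%02d-01", year, month + 1L))
  as.integer(format(first_next - 1L, "%d"))
}

#' First and last calendar day of a dekad
#'
#' @param d A [dekad()].
#' @return A `Date` of length 1.
#' @export
dekad_start <- function(d) {
  day <- c(1L, 11L, 21L)[d$dekad_of_month]
  as.Date(sprintf("%04d-%02d-%02d", d$year, d$month, day))
}

#' @rdname dekad_start
#' @export
dekad_end <- function(d) {
  if (d$dekad_of_month < 3L) {
    dekad_start(d) + 9L
  } else {
    as.Date(sprintf("%04d-%02d-%02d", d$year, d$month,
                    days_in_month(d$year, d$month)))
  }
}

#' Number of days spanned by a dekad
#'
#' The dekadal soil-moisture aggregation divides by this count (8, 9, 10 or
#' 11 days: the third dekad absorbs the variable month ends).
#'
#' @param d A [dekad()].
#' @return Integer in 8..11.
#' @export
dekad_day_count <- function(d) {
  as.integer(dekad_end(d) - dekad_start(d)) + 1L
}

#' Midpoint of a dekad, as a fractional day offset
#'
#' Used by the FAPAR compositor to measure temporal distance between a dekad
#' and the 8-day input composites. Returned as days since 1970-01-01
#' (fractional).
#'
#' @param d A [dekad()].
#' @return Numeric scalar.
#' @export
dekad_midpoint <- function(d) {
  (as.numeric(dekad_start(d)) + as.numeric(dekad_end(d))) / 2
}

#' All 36 dekads of a year, in order
#'
#' @param year Calendar year.
#' @return List of 36 [dekad()] objects whose day spans partition the year.
#' @export
dekads_in_year <- function(year) {
  stopifnot(year >= 1)
  lapply(1:36, function(o) dekad(year, o))
}

#' Dekad containing a calendar date
#'
#' @param date A `Date` (or string coercible to one).
#' @return The unique [dekad()] whose span contains `date`.
#' @export
dekad_of_date <- function(date) {
  date <- as.Date(date)
  stopifnot(length(date) == 1L, !is.na(date))
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  day <- as.integer(format(date, "%d"))
  dom <- if (day <= 10L) 1L else if (day <= 20L) 2L else 3L
  dekad(y, month = m, dekad_of_month = dom)
}

#' Neighbouring dekads
#'
#' `previous_dekad()` and `next_dekad()` cross year boundaries (ordinal 1 of
#' year Y is preceded by ordinal 36 of year Y-1), supporting the classifier's
#' T-1 state lookups and the snow-mask imputation chain.
#'
#' @param d A [dekad()].
#' @return A [dekad()].
#' @export
previous_dekad <- function(d) {
  if (d$ordinal == 1L) dekad(d$year - 1L, 36L) else dekad(d$year, d$ordinal - 1L)
}

#' @rdname previous_dekad
#' @export
next_dekad <- function(d) {
  if (d$ordinal == 36L) dekad(d$year + 1L, 1L) else dekad(d$year, d$ordinal + 1L)
}

#' Inclusive sequence of dekads
#'
#' @param from,to [dekad()] bounds, `from` not after `to`.
#' @return List of dekads from `from` to `to` inclusive.
#' @export
dekad_seq <- function(from, to) {
  a <- from$year * 36L + from$ordinal
  b <- to$year * 36L + to$ordinal
  stopifnot(a <= b)
  lapply(a:b, function(s) dekad((s - 1L) %/% 36L, (s - 1L) %% 36L + 1L))
}
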