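#' Add whole calendar years to a date
#'
#' Birthday-anniversary arithmetic: the result has the same month and day,
#' `n` years on. A 29 February anniversary rolls forward to 1 March in
#' non-leap years, so every child has exactly one anniversary per year.
#'
#' @param date a `Date` vector.
#' @param n integer number of years to add (scalar or vector recycled
#'   against `date`).
#' @return a `Date` vector.
#' @examples
#' add_years(as.Date("2004-03-15"), 11)
#' add_years(as.Date("2004-02-29"), 1)  # 2005-03-01
#' @export
add_years <- function(date, n) {
  stopifnot(inherits(date, "Date"))
  out <- rep(as.Date(NA), length(date))
  ok <- !is.na(date)
  if (!any(ok)) return(out)
  lt <- as.POSIXlt(date[ok])
  y <- lt$year + 1900L + as.integer(rep_len(n, length(date))[ok])
  cand <- as.Date(sprintf("%04d-%02d-%02d", y, lt$mon + 1L, lt$mday),
                  format = "%Y-%m-%d")
  roll <- is.na(cand)  # only 29 Feb in a non-leap target year
  cand[roll] <- as.Date(sprintf("%04d-03-01", y[roll]))
  out[ok] <- cand
  out
}

#' Age in completed years at an event
#'
#' Calendar (birthday-anniversary) age: the number of whole birthdays that
#' have passed on or before `event_date`. Leap-day births use the
#' roll-forward rule of [add_years()].
#'
#' @param birth_date,event_date `Date` vectors, recycled to a common length;
#'   `event_date` must not precede `birth_date`.
#' @return integer vector of completed years.
#' @examples
#' age_in_years(as.Date("2004-03-15"), as.Date("2009-03-14"))  # 4
#' age_in_years(as.Date("2004-03-15"), as.Date("2009-03-15"))  # 5
#' @export
age_in_years <- function(birth_date, event_date) {
  n <- max(length(birth_date), length(event_date))
  birth_date <- rep_len(birth_date, n)
  event_date <- rep_len(event_date, n)
  if (any(event_date < birth_date, na.rm = TRUE))
    stop("event_date precedes birth_date")
  yrs <- as.POSIXlt(event_date)$year - as.POSIXlt(birth_date)$year
  anniv <- add_years(birth_date, yrs)
  as.integer(yrs - (anniv > event_date))
}

#' Academic-year start year of a date
#'
#' English academic years run 1 September to 31 August; a date in
#' September--December belongs to the academic year starting that calendar
#' year, January--August to the one starting the previous calendar year.
#'
#' @param date a `Date` vector.
#' @return integer vector: calendar year of the 1 September opening the
#'   academic year containing `date`.
#' @export
academic_year_start <- function(date) {
  lt <- as.POSIXlt(date)
  as.integer(lt$year + 1900L - (lt$mon + 1L < 9L))
}

#' Academic-year label, e.g. "2009/10"
#' @param start_year integer vector of academic-year start years.
#' @return character labels `"YYYY/YY"`.
#' @export
academic_year_label <- function(start_year) {
  sprintf("%d/%02d", start_year, (start_year + 1L) %% 100L)
}

#' Date on which a child starts Year 1
#'
#' Year 1 is the first compulsory school year; it begins on the
#' 1 September of the academic year in which the child turns 6. A child
#' born between 1 September of year Y and 31 August of year Y+1 therefore
#' starts Year 1 on 1 September of year Y+6 (age 5, turning 6 during the
#' year; a child born exactly on 1 September turns 6 on day one).
#'
#' @param birth_date a `Date` vector.
#' @return a `Date` vector of 1 September dates.
#' @examples
#' year1_start_date(as.Date("2003-09-01"))  # 2009-09-01
#' year1_start_date(as.Date("2004-08-31"))  # 2009-09-01
#' @export
year1_start_date <- function(birth_date) {
  as.Date(sprintf("%d-09-01", academic_year_start(birth_date) + 6L))
}
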