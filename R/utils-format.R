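#' Round half away from zero at a fixed precision
#'
#' Display rounding for tables: 0.05 at 1 dp rounds to 0.1 (base R's
#' `round()` uses round-half-even). Used for all printed percentages and
#' rates.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a total, at display precision
#'
#' @param n numerator count(s).
#' @param total denominator.
#' @param digits decimal places (default 1, the convention for published
#'   cohort tables).
#' @return numeric percentage(s), half-up rounded.
#' @examples
#' prop_pct(127534, 3580225)  # 3.6
#' @export
prop_pct <- function(n, total, digits = 1) {
  round_half_up(100 * n / total, digits)
}

#' Events per 100 person-years
#' @param n_events event count(s).
#' @param person_years person-years at risk.
#' @param digits decimal places for display (default 2); `NULL` for full
#'   precision.
#' @return numeric rate(s).
#' @export
rate_per_100py <- function(n_events, person_years, digits = 2) {
  r <- 100 * n_events / person_years
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Rate ratio against a reference rate
#' @param rate,reference numeric rates on the same scale.
#' @param digits decimal places for display (default 2); `NULL` for full
#'   precision.
#' @return numeric ratio(s).
#' @examples
#' rate_ratio(34.24, 3.42)  # 10.01
#' @export
rate_ratio <- function(rate, reference, digits = 2) {
  rr <- rate / reference
  if (is.null(digits)) rr else round_half_up(rr, digits)
}

# internal: message helper respecting option(neurophen.quiet)
.np_msg <- function(...) {
  if (!isTRUE(getOption("neurophen.quiet", FALSE))) message(...)
  invisible(NULL)
}
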