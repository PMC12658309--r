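# Birth-cohort construction and the nested primary-school cohort.

#' Build the birth cohort with follow-up windows
#'
#' Every patient born within `birth_window` becomes a member, followed up
#' from birth until death or the 11th birthday (whichever is first). The
#' 11th birthday is computed calendar-wise, with 29 February anniversaries
#' rolling to 1 March in non-leap years.
#'
#' @param patients data.frame with `patient_id`, `birth_date` (unique by
#'   id).
#' @param deaths data.frame with `patient_id`, `death_date` (at most one
#'   row per patient); may have zero rows.
#' @param birth_window inclusive `Date` bounds of eligible births.
#' @return data.frame of class `neuro_cohort`: `patient_id`, `birth_date`,
#'   `death_date`, `eleventh_birthday`, `followup_end`.
#' @export
build_birth_cohort <- function(patients, deaths,
                               birth_window = as.Date(c("2003-09-01",
                                                        "2009-08-31"))) {
  pt <- as.data.table(patients)
  if (anyDuplicated(pt$patient_id)) stop("patients are not unique by patient_id")
  dd <- as.data.table(deaths)
  if (nrow(dd) && anyDuplicated(dd$patient_id))
    stop("more than one death record for patient(s): ",
         paste(dd$patient_id[duplicated(dd$patient_id)], collapse = ", "))
  co <- pt[birth_date >= birth_window[1] & birth_date <= birth_window[2],
           .(patient_id, birth_date)]
  if (nrow(dd)) co[dd, on = "patient_id", death_date := i.death_date]
  else co[, death_date := as.Date(NA)]
  bad <- co[!is.na(death_date) & death_date < birth_date]
  if (nrow(bad))
    stop("death before birth for patient(s): ",
         paste(bad$patient_id, collapse = ", "))
  co[, eleventh_birthday := add_years(birth_date, 11L)]
  co[, followup_end := pmin(eleventh_birthday, death_date, na.rm = TRUE)]
  setDF(co)
  class(co) <- c("neuro_cohort", "data.frame")
  co
}

#' Flag the nested primary-school cohort
#'
#' Applies the exclusion cascade to the birth cohort, in order: children
#' who died before their Year-1 start date (the 1 September of the
#' academic year in which they turn 6), then children with no linked
#' school record at all, then children with no Year-1 enrolment record.
#' Each excluded child carries the first applicable reason; members of the
#' school cohort carry reason `"none"`.
#'
#' @param cohort a [build_birth_cohort()] result.
#' @param school_records data.frame with `patient_id`, `academic_year`
#'   (`"YYYY/YY"`), `year_group` (`"R"`, `"1"`..`"6"`).
#' @param enrolment_rule `"expected_year"` (default): Year-1 enrolment
#'   must fall in the child's expected academic year; `"any_year"`: a
#'   Year-1 record in any academic year counts (covers year-repeaters,
#'   for whom the convention is not otherwise defined).
#' @return the cohort with columns `year1_start`, `in_school_cohort` and
#'   `school_exclusion_reason` added.
#' @export
build_school_cohort <- function(cohort, school_records,
                                enrolment_rule = c("expected_year", "any_year")) {
  enrolment_rule <- match.arg(enrolment_rule)
  co <- as.data.table(cohort)
  sr <- as.data.table(school_records)
  co[, year1_start := year1_start_date(birth_date)]
  co[, has_record := patient_id %in% sr$patient_id]
  y1 <- sr[year_group == "1"]
  if (enrolment_rule == "expected_year") {
    co[, expected_ay := academic_year_label(academic_year_start(year1_start))]
    y1 <- y1[co[, .(patient_id, academic_year = expected_ay)],
             on = c("patient_id", "academic_year"), nomatch = NULL]
    co[, expected_ay := NULL]
  }
  co[, enrolled_year1 := patient_id %in% y1$patient_id]
  co[, school_exclusion_reason := fcase(
    !is.na(death_date) & death_date < year1_start, "died_before_year1",
    !has_record, "no_linked_school_record",
    !enrolled_year1, "not_enrolled_year1",
    default = "none")]
  co[, in_school_cohort := school_exclusion_reason == "none"]
  co[, c("has_record", "enrolled_year1") := NULL]
  setDF(co)
  class(co) <- c("neuro_cohort", "data.frame")
  co
}

#' @export
print.neuro_cohort <- function(x, ...) {
  cat(sprintf("<neuro_cohort> %d children, births %s to %s\n", nrow(x),
              min(x$birth_date), max(x$birth_date)))
  if ("in_school_cohort" %in% names(x)) {
    cat(sprintf("  school cohort: %d (%.1f%%)\n", sum(x$in_school_cohort),
                100 * mean(x$in_school_cohort)))
    tab <- table(x$school_exclusion_reason[!x$in_school_cohort])
    for (nm in names(tab)) cat(sprintf("  excluded, %s: %d\n", nm, tab[[nm]]))
  }
  invisible(x)
}
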