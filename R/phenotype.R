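# Applying the neurodisability code list to each cohort member's hospital,
# mortality and birth-characteristic data.

.np_sources <- c("birth_characteristic", "admission_diagnosis",
                 "admission_procedure", "death_cause")

# lenient normalisation for observed codes: dirty values simply fail to match
.np_clean_codes <- function(x) {
  x <- toupper(gsub("[.[:space:]]", "", x))
  x[nzchar(x)]
}

#' Phenotype hospital-recorded neurodisability across a cohort
#'
#' Scans, for every cohort member, (i) every diagnosis position of every
#' admission starting before the 11th birthday, (ii) every procedure code
#' of those admissions, and (iii) every cause-of-death code for deaths
#' before the 11th birthday, matching each against the code list. In
#' addition, perinatal subgroups are triggered directly from structured
#' birth fields: gestational age below 27 completed weeks or birthweight
#' below 1000 g, dated at birth; missing fields never trigger. Events on
#' or after the 11th birthday are out of observation.
#'
#' @param cohort a [build_birth_cohort()] result.
#' @param admissions admissions data.frame (semicolon-delimited
#'   `diagnosis_codes`, `procedure_codes`); every `patient_id` must be a
#'   cohort member.
#' @param deaths deaths data.frame with semicolon-delimited `cause_codes`.
#' @param patients patients data.frame supplying `gestational_age_weeks`
#'   and `birthweight_g`.
#' @param codelist a `neuro_codelist`.
#' @param death_cause_dating `"death_date"` (default): evidence found only
#'   among causes of death is dated at death; `"exclude"`: such evidence
#'   still flags the child but contributes no date, so a child with no
#'   other dated evidence has age band `"none"`.
#' @param gestation_subgroup,birthweight_subgroup subgroup labels assigned
#'   by the birth-field triggers.
#' @return a list of class `neuro_phenotype`: `children` (one row per
#'   cohort member: `flagged`, `first_record_date`,
#'   `age_at_first_record_days`, `age_band` in `under5`/`five_to_ten`/
#'   `none`, `source` of the earliest record, semicolon-delimited
#'   `subgroups`) and `subgroups` (long table of per-subgroup first dates
#'   and sources).
#' @export
phenotype_cohort <- function(cohort, admissions, deaths, patients, codelist,
                             death_cause_dating = c("death_date", "exclude"),
                             gestation_subgroup = "extreme prematurity",
                             birthweight_subgroup = "extremely low birth weight") {
  death_cause_dating <- match.arg(death_cause_dating)
  stopifnot(inherits(codelist, "neuro_codelist"))
  co <- as.data.table(cohort)
  adm <- as.data.table(admissions)
  dd <- as.data.table(deaths)
  if (nrow(dd) && !"cause_codes" %in% names(dd)) dd[, cause_codes := ""]
  pt <- as.data.table(patients)

  unknown <- setdiff(adm$patient_id, co$patient_id)
  if (length(unknown))
    stop("admission(s) for unknown patient(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))

  adm[co, on = "patient_id", bday11 := i.eleventh_birthday]
  adm <- adm[admission_date < bday11]

  explode <- function(dt, col, src) {
    if (!nrow(dt)) return(data.table(patient_id = character(0),
                                     date = as.Date(character(0)),
                                     code = character(0), source = character(0)))
    codes <- strsplit(dt[[col]], ";", fixed = TRUE)
    nn <- lengths(codes)
    out <- data.table(patient_id = rep(dt$patient_id, nn),
                      date = rep(dt[[if ("admission_date" %in% names(dt))
                        "admission_date" else "death_date"]], nn),
                      code = unlist(codes, use.names = FALSE))
    out <- out[!is.na(code)]
    out[, code := toupper(gsub("[.[:space:]]", "", code))]
    out <- out[nzchar(code)]
    out[, source := src]
    out
  }
  dx <- explode(adm, "diagnosis_codes", "admission_diagnosis")
  pr <- explode(adm, "procedure_codes", "admission_procedure")
  if (nrow(dd)) {
    dc <- dd[co, on = "patient_id", nomatch = NULL,
             .(patient_id, death_date, cause_codes,
               bday11 = i.eleventh_birthday)][death_date < bday11]
    dc <- explode(dc, "cause_codes", "death_cause")
  } else dc <- explode(dd, "cause_codes", "death_cause")

  match_expand <- function(events, system) {
    if (!nrow(events)) return(events[, .(patient_id, date, source,
                                         subgroup = character(0))])
    uc <- unique(events$code)
    hits <- match_code(uc, system, codelist)
    map <- data.table(code = rep(uc, lengths(hits)),
                      subgroup = unlist(hits, use.names = FALSE))
    events[map, on = "code", allow.cartesian = TRUE, nomatch = NULL,
           .(patient_id, date, source, subgroup)]
  }
  hits <- rbind(match_expand(rbind(dx, dc), "ICD10"),
                match_expand(pr, "OPCS4"))

  # birth-characteristic triggers
  bt <- pt[co, on = "patient_id", nomatch = NULL,
           .(patient_id, birth_date = i.birth_date,
             gestational_age_weeks, birthweight_g)]
  trig <- rbind(
    bt[!is.na(gestational_age_weeks) & gestational_age_weeks < 27,
       .(patient_id, date = birth_date, source = "birth_characteristic",
         subgroup = gestation_subgroup)],
    bt[!is.na(birthweight_g) & birthweight_g < 1000,
       .(patient_id, date = birth_date, source = "birth_characteristic",
         subgroup = birthweight_subgroup)])
  hits <- rbind(hits, trig)

  if (death_cause_dating == "exclude")
    hits[source == "death_cause", date := as.Date(NA)]

  # per-subgroup first date; ties broken by source priority
  hits[, src_ord := match(source, .np_sources)]
  setorder(hits, patient_id, subgroup, date, src_ord, na.last = TRUE)
  sub_first <- hits[, .SD[1L], by = .(patient_id, subgroup),
                    .SDcols = c("date", "source", "src_ord")]
  setnames(sub_first, "date", "first_date")

  setorder(sub_first, patient_id, first_date, src_ord, na.last = TRUE)
  child <- sub_first[, .(
    first_record_date = if (all(is.na(first_date))) as.Date(NA)
                        else min(first_date, na.rm = TRUE),
    source = source[1L],
    subgroups = paste(sort(unique(subgroup)), collapse = ";")),
    by = patient_id]
  sub_first[, src_ord := NULL]

  children <- as.data.table(co)[, .(patient_id, birth_date)]
  children[, `:=`(flagged = FALSE, first_record_date = as.Date(NA),
                  source = NA_character_, subgroups = "")]
  children[child, on = "patient_id",
           `:=`(flagged = TRUE, first_record_date = i.first_record_date,
                source = i.source, subgroups = i.subgroups)]
  children[, age_at_first_record_days :=
             as.integer(first_record_date - birth_date)]
  children[, age_band := fcase(
    !flagged | is.na(first_record_date), "none",
    first_record_date < add_years(birth_date, 5L), "under5",
    default = "five_to_ten")]
  children[, birth_date := NULL]

  structure(list(children = setDF(children), subgroups = setDF(sub_first)),
            class = "neuro_phenotype")
}

#' @export
print.neuro_phenotype <- function(x, ...) {
  ch <- x$children
  cat(sprintf("<neuro_phenotype> %d children, %d flagged (%.1f%%)\n",
              nrow(ch), sum(ch$flagged), 100 * mean(ch$flagged)))
  if (any(ch$flagged)) {
    tab <- table(ch$age_band[ch$flagged])
    cat("  age at first record: ",
        paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
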