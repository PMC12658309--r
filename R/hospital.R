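# Spell linkage, person-time at risk, cumulative incidence, admission
# rates and rate ratios, mortality, birth-admission length.

.np_default_methods <- list(
  elective = c("11", "12", "13"),
  emergency = c("21", "22", "23", "24", "25", "2A", "2B"),
  birth = "82")

.np_pt_bands <- c("under1", "one_to_four", "five_to_ten", "under11")

# age band of an event date relative to birth (completed years)
.np_age_band <- function(birth, date) {
  a <- age_in_years(birth, date)
  fcase(a < 1L, "under1", a < 5L, "one_to_four", a < 11L, "five_to_ten",
        default = NA_character_)
}

#' Link admissions into continuous inpatient spells
#'
#' An admission starting on the day of a previous discharge (a hospital
#' transfer), or lying wholly within an earlier admission's dates, belongs
#' to the same period of continuous hospital care; merging is transitive.
#' Admissions that overlap an earlier one without being nested or same-day
#' contiguous are merged too, with a warning (dirty-data contract). The
#' spell's planned/unplanned/birth type comes from the earliest
#' information recorded: the admission-method code of its earliest
#' constituent admission.
#'
#' @param admissions admissions data.frame (any number of patients).
#' @param method_codes list mapping admission-method codes to `elective`,
#'   `emergency` and `birth` classes; anything else is `other`.
#' @return data.frame of spells: `spell_id`, `patient_id`, `start_date`,
#'   `end_date`, `spell_type` (`planned`/`unplanned`/`birth`/`other`),
#'   `n_admissions`, `admission_ids` (semicolon-delimited, date order),
#'   `has_birth_admission`, `died_in_hospital`.
#' @export
link_spells <- function(admissions, method_codes = .np_default_methods) {
  a <- as.data.table(admissions)
  if (!nrow(a))
    return(data.frame(spell_id = character(0), patient_id = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      spell_type = character(0), n_admissions = integer(0),
                      admission_ids = character(0),
                      has_birth_admission = logical(0),
                      died_in_hospital = logical(0)))
  if (any(a$discharge_date < a$admission_date))
    stop("discharge before admission for admission(s): ",
         paste(utils::head(a$admission_id[a$discharge_date < a$admission_date],
                           5L), collapse = ", "))
  setorder(a, patient_id, admission_date, discharge_date, admission_id)
  a[, prev_end := shift(cummax(as.numeric(discharge_date)), fill = -Inf),
    by = patient_id]
  a[, new_spell := as.numeric(admission_date) > prev_end]
  dirty <- a[!new_spell & as.numeric(admission_date) < prev_end &
               as.numeric(discharge_date) > prev_end]
  if (nrow(dirty))
    warning(sprintf("merged %d admission(s) overlapping an earlier admission without same-day contiguity or nesting",
                    nrow(dirty)))
  a[, spell_num := cumsum(new_spell), by = patient_id]
  sp <- a[, .(
    start_date = min(admission_date), end_date = max(discharge_date),
    first_method = admission_method_code[1L],
    n_admissions = .N,
    admission_ids = paste(admission_id, collapse = ";"),
    has_birth_admission = any(is_birth_admission),
    died_in_hospital = any(died_in_hospital)),
    by = .(patient_id, spell_num)]
  sp[, spell_type := fcase(
    first_method %in% method_codes$elective, "planned",
    first_method %in% method_codes$emergency, "unplanned",
    first_method %in% method_codes$birth, "birth",
    default = "other")]
  sp[, spell_id := sprintf("S%07d", .I)]
  out <- sp[, .(spell_id, patient_id, start_date, end_date, spell_type,
                n_admissions, admission_ids, has_birth_admission,
                died_in_hospital)]
  setDF(out)
}

#' Person-time at risk by age band, excluding in-hospital days
#'
#' For each cohort member, total follow-up days from birth to death or the
#' 11th birthday, split at exact birthday anniversaries into bands `<1`,
#' `1-4` and `5-10` (plus the `<11` aggregate), with days spent in
#' hospital subtracted. A spell contributes `end - start` days clipped to
#' each band and to follow-up, so a same-day spell contributes zero days;
#' linked spells are disjoint, so no day is counted twice.
#'
#' @param cohort a [build_birth_cohort()] result.
#' @param spells a [link_spells()] result.
#' @return long data.frame: `patient_id`, `band` (`under1`,
#'   `one_to_four`, `five_to_ten`, `under11`), `days_total`,
#'   `days_in_hospital`, `days_at_risk`.
#' @export
compute_person_time <- function(cohort, spells) {
  co <- as.data.table(cohort)
  sp <- as.data.table(spells)
  bands <- data.table(band = .np_pt_bands[1:3], lo_y = c(0L, 1L, 5L),
                      hi_y = c(1L, 5L, 11L))
  cb <- co[rep(seq_len(nrow(co)), each = nrow(bands)),
           .(patient_id, birth_date, followup_end)]
  cb[, `:=`(band = rep(bands$band, nrow(co)),
            lo_y = rep(bands$lo_y, nrow(co)),
            hi_y = rep(bands$hi_y, nrow(co)))]
  cb[, `:=`(lo = add_years(birth_date, lo_y), hi = add_years(birth_date, hi_y))]
  cb[, days_total := pmax(0, as.numeric(pmin(hi, followup_end) - lo))]

  if (nrow(sp)) {
    ov <- sp[, .(patient_id, start_date, end_date)][
      cb, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    ov[, d := pmax(0, as.numeric(
      pmin(end_date, hi, followup_end) - pmax(start_date, lo)))]
    hosp <- ov[, .(days_in_hospital = sum(d)), by = .(patient_id, band)]
    cb[hosp, on = c("patient_id", "band"), days_in_hospital := i.days_in_hospital]
  }
  if (!"days_in_hospital" %in% names(cb)) cb[, days_in_hospital := 0]
  cb[is.na(days_in_hospital), days_in_hospital := 0]
  cb[, days_at_risk := days_total - days_in_hospital]

  out <- cb[, .(patient_id, band, days_total, days_in_hospital, days_at_risk)]
  agg <- out[, .(band = "under11", days_total = sum(days_total),
                 days_in_hospital = sum(days_in_hospital),
                 days_at_risk = sum(days_at_risk)), by = patient_id]
  out <- rbind(out, agg)
  out[, band := factor(band, levels = .np_pt_bands)]
  setorder(out, patient_id, band)
  out[, band := as.character(band)]
  setDF(out)
}

# phenotype-status membership groups used by the summary operations:
# "none" (reference), "any", and the age-at-first-record subsets
.np_status_groups <- function(cohort, phenotype) {
  ch <- as.data.table(phenotype$children)
  rbind(
    ch[flagged == FALSE, .(group = "none", patient_id)],
    ch[flagged == TRUE, .(group = "any", patient_id)],
    ch[age_band == "under5", .(group = "under5", patient_id)],
    ch[age_band == "five_to_ten", .(group = "five_to_ten", patient_id)])
}

.np_subgroup_groups <- function(cohort, phenotype) {
  ch <- as.data.table(phenotype$children)
  sg <- as.data.table(phenotype$subgroups)
  rbind(ch[flagged == FALSE, .(group = "none", patient_id)],
        sg[, .(group = subgroup, patient_id)])
}

#' Cumulative incidence of first recorded neurodisability by age
#'
#' For each age threshold, both quantities the literature reports: the
#' proportion of children with a first qualifying record before the
#' threshold birthday (cases divided by cohort size) and the incidence
#' rate (cases divided by person-years at risk, where person-time accrues
#' from birth to the first record, death, or the threshold birthday,
#' whichever is earliest). The threshold is strict: a first record exactly
#' on the threshold birthday does not count.
#'
#' @param cohort a [build_birth_cohort()] result.
#' @param phenotype a [phenotype_cohort()] result.
#' @param age_thresholds integer ages in years, each at most 11.
#' @return data.frame: `age_threshold`, `n_children`, `n_cases`,
#'   `proportion`, `pct`, `person_years`, `rate_per_100py`.
#' @export
cumulative_incidence <- function(cohort, phenotype, age_thresholds = c(1, 5, 11)) {
  if (any(age_thresholds > 11))
    stop("age thresholds beyond the 11-year follow-up are not observable")
  co <- as.data.table(cohort)
  ch <- as.data.table(phenotype$children)
  co[ch, on = "patient_id", first_record_date := i.first_record_date]
  out <- lapply(age_thresholds, function(t) {
    tb <- add_years(co$birth_date, as.integer(t))
    case <- !is.na(co$first_record_date) & co$first_record_date < tb
    end <- pmin(co$first_record_date, co$death_date, tb, na.rm = TRUE)
    py <- sum(as.numeric(end - co$birth_date)) / 365.25
    data.frame(age_threshold = t, n_children = nrow(co), n_cases = sum(case),
               proportion = sum(case) / nrow(co),
               pct = prop_pct(sum(case), nrow(co)),
               person_years = py,
               rate_per_100py = rate_per_100py(sum(case), py))
  })
  do.call(rbind, out)
}

#' Planned and unplanned admission rates and rate ratios
#'
#' Spells (not raw admissions) are the counted unit by default; each spell
#' is attributed to the age band of its start date. Birth spells are
#' excluded from the planned/unplanned counts unless requested. Rates are
#' events per 100 person-years at risk (hospital days excluded from the
#' denominator); the rate ratio compares each group with the no-phenotype
#' reference. A cell with zero person-years yields a missing rate with a
#' log message.
#'
#' @param cohort a [build_birth_cohort()] result.
#' @param spells a [link_spells()] result.
#' @param person_time a [compute_person_time()] result.
#' @param phenotype a [phenotype_cohort()] result.
#' @param by `"status"` (none / any / under5 / five_to_ten) or
#'   `"subgroup"` (none plus each hospital subgroup; groups overlap).
#' @param numerator `"spells"` (default) or `"admissions"` (count
#'   constituent admissions instead of linked spells).
#' @param include_birth_spells if `TRUE`, birth-type spells are reported
#'   as an additional `spell_type = "birth"` stratum.
#' @return data.frame: `group`, `spell_type`, `band`, `n_events`,
#'   `person_years`, `rate_per_100py`, `rate_ratio` (NA for the
#'   reference).
#' @export
admission_rates <- function(cohort, spells, person_time, phenotype,
                            by = c("status", "subgroup"),
                            numerator = c("spells", "admissions"),
                            include_birth_spells = FALSE) {
  by <- match.arg(by)
  numerator <- match.arg(numerator)
  co <- as.data.table(cohort)
  sp <- as.data.table(spells)
  pt <- as.data.table(person_time)
  groups <- if (by == "status") .np_status_groups(cohort, phenotype)
            else .np_subgroup_groups(cohort, phenotype)

  types <- c("planned", "unplanned", if (include_birth_spells) "birth")
  sp <- sp[spell_type %in% types]
  sp[co, on = "patient_id", `:=`(birth_date = i.birth_date,
                                 bday11 = i.eleventh_birthday)]
  sp <- sp[start_date < bday11]
  sp[, band := .np_age_band(birth_date, start_date)]
  sp[, w := if (numerator == "spells") 1L else n_admissions]

  ev <- sp[groups, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL,
           .(group, spell_type, band, w)]
  ev <- rbind(ev, copy(ev)[, band := "under11"])
  nev <- ev[, .(n_events = sum(w)), by = .(group, spell_type, band)]

  gm <- merge(as.data.table(groups), pt, by = "patient_id",
              allow.cartesian = TRUE)
  pyt <- gm[, .(person_years = sum(days_at_risk) / 365.25), by = .(group, band)]

  grid <- CJ(group = unique(groups$group), spell_type = types,
             band = .np_pt_bands, unique = TRUE)
  grid <- merge(grid, nev, by = c("group", "spell_type", "band"), all.x = TRUE)
  grid <- merge(grid, pyt, by = c("group", "band"), all.x = TRUE)
  grid[is.na(n_events), n_events := 0L]
  grid[is.na(person_years), person_years := 0]
  zero <- grid[person_years <= 0 & n_events >= 0]
  if (nrow(zero))
    .np_msg(sprintf("%d rate cell(s) with zero person-years left missing",
                    nrow(zero)))
  grid[, rate_per_100py := fifelse(person_years > 0,
                                   100 * n_events / person_years, NA_real_)]
  ref <- grid[group == "none", .(spell_type, band, ref_rate = rate_per_100py)]
  grid[ref, on = c("spell_type", "band"), ref_rate := i.ref_rate]
  grid[, rate_ratio := fifelse(group == "none", NA_real_,
                               rate_per_100py / ref_rate)]
  grid[, ref_rate := NULL]
  grid[, group := factor(group, levels = unique(groups$group))]
  grid[, band := factor(band, levels = .np_pt_bands)]
  setorder(grid, spell_type, group, band)
  grid[, `:=`(group = as.character(group), band = as.character(band))]
  setDF(grid)
}

#' Deaths and death proportions by phenotype group and age at death
#'
#' Denominators are group sizes; band membership follows completed age at
#' death. Deaths on or after the 11th birthday fall outside follow-up and
#' are not counted.
#'
#' @param cohort a [build_birth_cohort()] result.
#' @param phenotype a [phenotype_cohort()] result.
#' @return data.frame: `group`, `band` (`under1`, `one_to_four`,
#'   `five_to_ten`, `under11`), `n_group`, `n_deaths`, `pct` (1 dp).
#' @export
mortality_summary <- function(cohort, phenotype) {
  co <- as.data.table(cohort)
  groups <- .np_status_groups(cohort, phenotype)
  dd <- co[!is.na(death_date) & death_date < eleventh_birthday]
  dd[, band := .np_age_band(birth_date, death_date)]
  gm <- merge(groups, dd[, .(patient_id, band)], by = "patient_id",
              all.x = TRUE)
  sizes <- groups[, .(n_group = .N), by = group]
  counts <- gm[!is.na(band), .(n_deaths = .N), by = .(group, band)]
  counts <- rbind(counts,
                  gm[!is.na(band), .(band = "under11", n_deaths = .N),
                     by = group])
  grid <- CJ(group = unique(groups$group), band = .np_pt_bands, unique = TRUE)
  grid <- merge(grid, counts, by = c("group", "band"), all.x = TRUE)
  grid[is.na(n_deaths), n_deaths := 0L]
  grid <- merge(grid, sizes, by = "group")
  grid[, pct := prop_pct(n_deaths, n_group)]
  grid[, group := factor(group, levels = unique(groups$group))]
  grid[, band := factor(band, levels = .np_pt_bands)]
  setorder(grid, group, band)
  grid[, `:=`(group = as.character(group), band = as.character(band))]
  setDF(grid[, .(group, band, n_group, n_deaths, pct)])
}

#' Length of birth admission by phenotype group
#'
#' The birth spell is the linked spell containing the birth admission; its
#' length is `end - start` in days (a same-day discharge is 0 days).
#' Children with no birth admission are excluded from the statistic, with
#' a logged count. Quartiles use the default (type 7) convention.
#'
#' @param cohort a [build_birth_cohort()] result.
#' @param spells a [link_spells()] result.
#' @param phenotype a [phenotype_cohort()] result.
#' @return data.frame per group: `n`, `mean`, `sd`, `median`, `q25`,
#'   `q75`.
#' @export
birth_admission_length <- function(cohort, spells, phenotype) {
  sp <- as.data.table(spells)[has_birth_admission == TRUE]
  groups <- .np_status_groups(cohort, phenotype)
  co <- as.data.table(cohort)
  n_missing <- nrow(co) - length(unique(sp$patient_id))
  if (n_missing > 0)
    .np_msg(sprintf("%d child(ren) with no birth admission excluded from birth-admission length", n_missing))
  sp[, len := as.numeric(end_date - start_date)]
  bl <- sp[, .(len = len[1L]), by = patient_id]  # one birth spell per child
  gm <- merge(groups, bl, by = "patient_id")
  out <- gm[, .(n = .N, mean = mean(len), sd = stats::sd(len),
                median = stats::median(len),
                q25 = unname(quantile(len, 0.25)),
                q75 = unname(quantile(len, 0.75))), by = group]
  setDF(out)
}
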