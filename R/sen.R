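# School-recorded special educational needs (SEN) outcomes in the nested
# primary-school cohort.

.np_sen_levels <- c("none", "support", "ehcp")
.np_year_groups <- c("R", "1", "2", "3", "4", "5", "6")

#' Per-pupil SEN provision history over primary school
#'
#' Summarises each school-cohort member's Reception--Year 6 records: the
#' provision level observed in Reception, Year 1, Year 3 and Year 6
#' (`"not_enrolled"` when absent), whether SEN support or an EHCP was ever
#' recorded, the hierarchical highest-ever level (EHCP over support over
#' none), and the set of primary needs ever recorded in SEN years. A pupil
#' missing later years still contributes from the years observed.
#'
#' @param school_cohort a [build_school_cohort()] result.
#' @param school_records school-census data.frame (`patient_id`,
#'   `year_group`, `sen_level`, `primary_need`).
#' @return data.frame of class `neuro_sen_history`, one row per
#'   school-cohort member: `level_R`, `level_1`, `level_3`, `level_6`,
#'   `ever_support`, `ever_ehcp`, `highest_ever`, `primary_needs_ever`
#'   (semicolon-delimited).
#' @export
sen_history <- function(school_cohort, school_records) {
  co <- as.data.table(school_cohort)[in_school_cohort == TRUE]
  sr <- as.data.table(school_records)[patient_id %in% co$patient_id &
                                        year_group %in% .np_year_groups]
  bad <- setdiff(unique(sr$sen_level), .np_sen_levels)
  if (length(bad)) stop("unknown sen_level value(s): ", paste(bad, collapse = ", "))

  out <- co[, .(patient_id)]
  for (g in c("R", "1", "3", "6")) {
    lv <- sr[year_group == g, .(patient_id, lev = sen_level)]
    col <- paste0("level_", g)
    out[, (col) := "not_enrolled"]
    out[lv, on = "patient_id", (col) := i.lev]
  }
  ever <- sr[, .(ever_support = any(sen_level == "support"),
                 ever_ehcp = any(sen_level == "ehcp"),
                 primary_needs_ever = paste(
                   sort(unique(primary_need[sen_level != "none" &
                                              primary_need != "none"])),
                   collapse = ";")), by = patient_id]
  out[, `:=`(ever_support = FALSE, ever_ehcp = FALSE, primary_needs_ever = "")]
  out[ever, on = "patient_id",
      `:=`(ever_support = i.ever_support, ever_ehcp = i.ever_ehcp,
           primary_needs_ever = i.primary_needs_ever)]
  out[, highest_ever := fcase(ever_ehcp, "ehcp", ever_support, "support",
                              default = "none")]
  setDF(out)
  class(out) <- c("neuro_sen_history", "data.frame")
  out
}

# membership restricted to the school cohort
.np_school_groups <- function(school_cohort, phenotype) {
  ids <- school_cohort$patient_id[school_cohort$in_school_cohort]
  g <- .np_status_groups(NULL, phenotype)
  as.data.table(g)[patient_id %in% ids]
}

#' Highest-ever SEN provision by phenotype group
#'
#' Cumulative provision over primary school with the Year-1-enrolled
#' school cohort as the denominator. "Any provision" counts pupils with
#' support or an EHCP in any primary year; the ever-support and ever-EHCP
#' categories overlap by design (support commonly precedes an EHCP), while
#' the `highest_*` hierarchy (EHCP over support over none) partitions each
#' group.
#'
#' @param school_cohort a [build_school_cohort()] result.
#' @param history a [sen_history()] result.
#' @param phenotype a [phenotype_cohort()] result.
#' @return data.frame per group (`none`, `any`, `under5`, `five_to_ten`):
#'   pupil count, counts and percentages for any provision, ever support,
#'   ever EHCP, and the hierarchical highest-ever levels.
#' @export
sen_ever_summary <- function(school_cohort, history, phenotype) {
  groups <- .np_school_groups(school_cohort, phenotype)
  h <- as.data.table(history)
  gm <- merge(groups, h, by = "patient_id")
  out <- gm[, .(
    n_pupils = .N,
    n_any = sum(ever_support | ever_ehcp),
    n_ever_support = sum(ever_support),
    n_ever_ehcp = sum(ever_ehcp),
    n_highest_none = sum(highest_ever == "none"),
    n_highest_support = sum(highest_ever == "support"),
    n_highest_ehcp = sum(highest_ever == "ehcp")), by = group]
  out[, `:=`(pct_any = prop_pct(n_any, n_pupils),
             pct_ever_support = prop_pct(n_ever_support, n_pupils),
             pct_ever_ehcp = prop_pct(n_ever_ehcp, n_pupils),
             pct_highest_none = prop_pct(n_highest_none, n_pupils),
             pct_highest_support = prop_pct(n_highest_support, n_pupils),
             pct_highest_ehcp = prop_pct(n_highest_ehcp, n_pupils))]
  out[, group := factor(group, levels = c("none", "any", "under5",
                                          "five_to_ten"))]
  setorder(out, group)
  out[, group := as.character(group)]
  setDF(out)
}

#' SEN provision by school year and phenotype group
#'
#' Per-year proportions with year-specific enrolment counts as
#' denominators (enrolment can change between academic years, so each
#' year's denominator differs; a pupil not enrolled in a year is excluded
#' from that year's denominator).
#'
#' @param school_cohort a [build_school_cohort()] result.
#' @param school_records school-census data.frame.
#' @param phenotype a [phenotype_cohort()] result.
#' @param year_groups subset of `"R"`, `"1"`..`"6"` to report (default
#'   Reception, Year 1, Year 3, Year 6).
#' @return data.frame: `group`, `year_group`, `n_enrolled`, `n_support`,
#'   `n_ehcp`, `n_any`, `pct_support`, `pct_ehcp`, `pct_any`.
#' @export
sen_by_year <- function(school_cohort, school_records, phenotype,
                        year_groups = c("R", "1", "3", "6")) {
  bad <- setdiff(year_groups, .np_year_groups)
  if (length(bad))
    stop("year group(s) outside Reception..Year 6: ", paste(bad, collapse = ", "))
  groups <- .np_school_groups(school_cohort, phenotype)
  sr <- as.data.table(school_records)[year_group %in% year_groups]
  gm <- sr[groups, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
  out <- gm[, .(n_enrolled = .N,
                n_support = sum(sen_level == "support"),
                n_ehcp = sum(sen_level == "ehcp"),
                n_any = sum(sen_level != "none")),
            by = .(group, year_group)]
  out[, `:=`(pct_support = prop_pct(n_support, n_enrolled),
             pct_ehcp = prop_pct(n_ehcp, n_enrolled),
             pct_any = prop_pct(n_any, n_enrolled))]
  out[, group := factor(group, levels = c("none", "any", "under5",
                                          "five_to_ten"))]
  out[, year_group := factor(year_group, levels = .np_year_groups)]
  setorder(out, group, year_group)
  out[, `:=`(group = as.character(group), year_group = as.character(year_group))]
  setDF(out)
}

#' Concordance between hospital subgroups and school-recorded needs
#'
#' For each hospital-recorded subgroup with a corresponding
#' school-recorded primary-need category, the proportion of school-cohort
#' children in the subgroup whose school records ever carry that need.
#' The school "learning disability" category corresponds to the census
#' severe and profound/multiple learning-difficulty codes grouped
#' together. A subgroup with no school-cohort members yields a missing
#' proportion.
#'
#' @param school_cohort a [build_school_cohort()] result.
#' @param history a [sen_history()] result.
#' @param phenotype a [phenotype_cohort()] result.
#' @param need_map named character vector mapping hospital subgroup labels
#'   to school primary-need categories; defaults to the package's
#'   taxonomy mapping.
#' @return data.frame: `subgroup`, `school_need`, `n_subgroup`,
#'   `n_with_need`, `proportion`.
#' @export
sen_concordance <- function(school_cohort, history, phenotype,
                            need_map = .np_subgroup_need_map) {
  ids <- school_cohort$patient_id[school_cohort$in_school_cohort]
  sg <- as.data.table(phenotype$subgroups)[patient_id %in% ids &
                                             subgroup %in% names(need_map)]
  h <- as.data.table(history)
  out <- rbindlist(lapply(names(need_map), function(s) {
    members <- unique(sg[subgroup == s, patient_id])
    need <- need_map[[s]]
    hh <- h[patient_id %in% members]
    n_with <- sum(vapply(strsplit(hh$primary_needs_ever, ";", fixed = TRUE),
                         function(v) need %in% v, logical(1)))
    data.table(subgroup = s, school_need = need,
               n_subgroup = length(members), n_with_need = n_with,
               proportion = if (length(members)) n_with / length(members)
                            else NA_real_)
  }))
  setDF(out)
}
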