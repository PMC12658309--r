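# Publication-style output tables with disclosure control, and run
# orchestration for the whole pipeline.

.np_char_groups <- c("none", "any", "under5", "five_to_ten")

# band labels for the characteristics table
.np_gest_bands <- c("23-26", "27-31", "32-36", "37-40", ">=41", "Missing")
.np_bw_bands <- c("<1000", "1000-2499", "2500-3499", "3500-4499", ">=4500",
                  "Missing")
.np_month_pairs <- c("Sep-Oct", "Nov-Dec", "Jan-Feb", "Mar-Apr", "May-Jun",
                     "Jul-Aug")

#' Cohort characteristics by phenotype group
#'
#' Cross-tabulates baseline characteristics (sex, two-month birth period,
#' academic year of birth, gestational-age band, birthweight band,
#' maternal-age band) against phenotype groups (no phenotype, any, first
#' record under 5, first record 5--10). Missing data are retained as an
#' explicit `Missing` row in every variable block; percentages are within
#' column (group size as denominator), to 1 dp.
#'
#' @param cohort a [build_birth_cohort()] result.
#' @param phenotype a [phenotype_cohort()] result.
#' @param patients patients data.frame with the birth characteristics.
#' @return data.frame of class `neuro_char_table`: `variable`, `level`,
#'   then `n_<group>` and `pct_<group>` for each group.
#' @export
characteristics_table <- function(cohort, phenotype, patients) {
  co <- as.data.table(cohort)
  pt <- as.data.table(patients)
  groups <- .np_status_groups(cohort, phenotype)

  x <- merge(co[, .(patient_id, birth_date)],
             pt[, .(patient_id, sex, gestational_age_weeks, birthweight_g,
                    maternal_age_band)], by = "patient_id")
  mon <- as.POSIXlt(x$birth_date)$mon + 1L  # 1..12
  x[, `:=`(
    Sex = fcase(sex == "male", "Boys", sex == "female", "Girls",
                default = "Missing"),
    `Month of birth` = .np_month_pairs[((mon - 9L) %% 12L) %/% 2L + 1L],
    `Year of birth` = academic_year_label(academic_year_start(birth_date)),
    `Gestational age (weeks)` = fcase(
      is.na(gestational_age_weeks), "Missing",
      gestational_age_weeks <= 26, "23-26",
      gestational_age_weeks <= 31, "27-31",
      gestational_age_weeks <= 36, "32-36",
      gestational_age_weeks <= 40, "37-40",
      default = ">=41"),
    `Birthweight (g)` = fcase(
      is.na(birthweight_g), "Missing",
      birthweight_g < 1000, "<1000",
      birthweight_g < 2500, "1000-2499",
      birthweight_g < 3500, "2500-3499",
      birthweight_g < 4500, "3500-4499",
      default = ">=4500"),
    `Maternal age (years)` = fifelse(is.na(maternal_age_band), "Missing",
                                     maternal_age_band))]

  vars <- c("Sex", "Month of birth", "Year of birth",
            "Gestational age (weeks)", "Birthweight (g)",
            "Maternal age (years)")
  levels_of <- list(
    Sex = c("Boys", "Girls", "Missing"),
    `Month of birth` = .np_month_pairs,
    `Year of birth` = sort(unique(x$`Year of birth`)),
    `Gestational age (weeks)` = .np_gest_bands,
    `Birthweight (g)` = .np_bw_bands,
    `Maternal age (years)` = c("<20", "20-24", "25-29", "30-34", "35-39",
                               ">=40", "Missing"))

  gm <- merge(groups, x, by = "patient_id", allow.cartesian = TRUE)
  sizes <- as.data.table(groups)[, .(n_group = .N), by = group]

  out <- rbindlist(lapply(vars, function(v) {
    lv <- levels_of[[v]]
    tab <- gm[, .N, by = c("group", v)]
    setnames(tab, v, "level")
    grid <- CJ(group = .np_char_groups, level = lv)
    grid <- merge(grid, tab, by = c("group", "level"), all.x = TRUE)
    grid[is.na(N), N := 0L]
    grid <- merge(grid, sizes, by = "group", all.x = TRUE)
    grid[is.na(n_group), n_group := 0L]  # an empty group keeps its columns
    grid[, pct := fifelse(n_group > 0L, prop_pct(N, n_group), NA_real_)]
    wide <- dcast(grid, level ~ group, value.var = c("N", "pct"))
    setnames(wide, gsub("^N_", "n_", names(wide)))
    wide[, variable := v]
    wide[order(match(level, lv))]
  }), use.names = TRUE)
  cols <- c("variable", "level",
            paste0(rep(c("n_", "pct_"), each = length(.np_char_groups)),
                   .np_char_groups))
  out <- out[, cols, with = FALSE]
  setDF(out)
  attr(out, "group_sizes") <- setNames(sizes$n_group, sizes$group)
  class(out) <- c("neuro_char_table", "data.frame")
  out
}

#' Mask small counts in a vector of cell counts
#'
#' Primary suppression masks counts strictly between 0 and the threshold.
#' If exactly one cell in the vector is masked and the margin (the cells'
#' total) is published, the masked value could be recovered by
#' subtraction, so the smallest remaining cell is masked too (secondary,
#' complementary suppression).
#'
#' @param n integer vector of cell counts forming one margin group.
#' @param threshold counts below this (and above 0) are masked.
#' @param margin the published total for the group (default `sum(n)`);
#'   `NA` if no margin is published, disabling secondary suppression.
#' @return logical mask, `TRUE` where the cell must be suppressed.
#' @export
suppress_counts <- function(n, threshold = 10, margin = sum(n)) {
  mask <- !is.na(n) & n > 0 & n < threshold
  if (sum(mask) == 1L && !is.na(margin)) {
    others <- which(!mask & !is.na(n))
    if (length(others)) mask[others[order(n[others])][1L]] <- TRUE
  }
  mask
}

#' Apply small-cell suppression to a characteristics table
#'
#' Within each variable block and group column, counts below the
#' threshold are replaced by the token, with complementary suppression
#' where the column margin (the group size) would allow back-calculation;
#' percentages derived from suppressed counts are suppressed with them.
#'
#' @param tab a [characteristics_table()] result.
#' @param threshold suppression threshold (counts below it are masked).
#' @param token replacement string.
#' @return the table with count/percentage columns as character,
#'   suppressed cells replaced by `token`.
#' @export
apply_suppression <- function(tab, threshold = 10, token = "<10") {
  stopifnot(inherits(tab, "neuro_char_table"))
  out <- as.data.frame(tab)
  for (g in .np_char_groups) {
    ncol_ <- paste0("n_", g)
    pcol <- paste0("pct_", g)
    nchr <- format(out[[ncol_]], trim = TRUE, scientific = FALSE)
    pchr <- format(out[[pcol]], trim = TRUE)
    for (v in unique(out$variable)) {
      idx <- which(out$variable == v)
      mask <- suppress_counts(out[[ncol_]][idx], threshold = threshold)
      nchr[idx][mask] <- token
      pchr[idx][mask] <- token
    }
    out[[ncol_]] <- nchr
    out[[pcol]] <- pchr
  }
  class(out) <- "data.frame"
  out
}

#' Pipeline run configuration
#'
#' Bundles input locations, the code list, output directory and every
#' module switch into one validated object for [run_pipeline()].
#'
#' @param input_dir directory holding `patients.csv`, `admissions.csv`,
#'   `deaths.csv`, `school.csv` (ignored when `data` is given).
#' @param data optional in-memory list with the four tables (e.g. a
#'   [generate_cohort_data()] result).
#' @param codelist a `neuro_codelist` or a path to a code-list CSV;
#'   defaults to the package's illustrative list.
#' @param output_dir directory for output tables and `run.log`; `NULL`
#'   writes nothing.
#' @param birth_window inclusive `Date` bounds of the birth cohort.
#' @param enrolment_rule,death_cause_dating,numerator module switches, see
#'   [build_school_cohort()], [phenotype_cohort()], [admission_rates()].
#' @param method_codes admission-method vocabulary for [link_spells()].
#' @param suppression_threshold,suppression_token disclosure-control rule
#'   for the characteristics table.
#' @return a list of class `neuro_run_config`.
#' @export
run_config <- function(input_dir = NULL, data = NULL,
                       codelist = example_codelist(), output_dir = NULL,
                       birth_window = as.Date(c("2003-09-01", "2009-08-31")),
                       enrolment_rule = c("expected_year", "any_year"),
                       death_cause_dating = c("death_date", "exclude"),
                       numerator = c("spells", "admissions"),
                       method_codes = .np_default_methods,
                       suppression_threshold = 10,
                       suppression_token = "<10") {
  if (is.null(input_dir) && is.null(data))
    stop("one of input_dir or data is required")
  if (!is.null(input_dir) && is.null(data)) {
    for (f in paste0(c("patients", "admissions", "deaths", "school"), ".csv"))
      if (!file.exists(file.path(input_dir, f)))
        stop("missing input file: ", file.path(input_dir, f))
  }
  if (is.character(codelist)) codelist <- load_codelist(codelist)
  stopifnot(inherits(codelist, "neuro_codelist"))
  if (suppression_threshold < 0) stop("suppression threshold must be >= 0")
  structure(list(
    input_dir = input_dir, data = data, codelist = codelist,
    output_dir = output_dir, birth_window = birth_window,
    enrolment_rule = match.arg(enrolment_rule),
    death_cause_dating = match.arg(death_cause_dating),
    numerator = match.arg(numerator), method_codes = method_codes,
    suppression_threshold = suppression_threshold,
    suppression_token = suppression_token), class = "neuro_run_config")
}

#' Run the full phenotyping and outcomes pipeline
#'
#' Reads (or receives) the four linked tables, builds the birth and
#' school cohorts, phenotypes every member, links spells, computes
#' person-time, cumulative incidence, admission rates, mortality,
#' birth-admission length and the SEN outcomes, and assembles the
#' characteristics table with small-cell suppression. Deterministic given
#' the inputs. Row counts at every stage are logged; when `output_dir` is
#' set, all tables are written as CSV alongside `run.log`.
#'
#' @param config a [run_config()].
#' @return a list of class `neuro_run` with every intermediate and output
#'   table, plus `log` (character vector of stage messages).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "neuro_run_config"))
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log <<- c(log, line)
    .np_msg(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  data <- if (!is.null(config$data)) config$data
          else stage("read", read_datasets(config$input_dir))
  say("inputs: %d patients, %d admissions, %d deaths, %d school records",
      nrow(data$patients), nrow(data$admissions), nrow(data$deaths),
      nrow(data$school))

  cohort <- stage("cohort", build_birth_cohort(data$patients, data$deaths,
                                               config$birth_window))
  say("birth cohort: %d children", nrow(cohort))
  cohort <- stage("school_cohort",
                  build_school_cohort(cohort, data$school,
                                      config$enrolment_rule))
  excl <- table(cohort$school_exclusion_reason)
  say("school cohort: %d children (%s)", sum(cohort$in_school_cohort),
      paste(sprintf("%s=%d", names(excl), excl), collapse = ", "))

  phen <- stage("phenotype",
                phenotype_cohort(cohort, data$admissions, data$deaths,
                                 data$patients, config$codelist,
                                 config$death_cause_dating))
  say("phenotype: %d flagged of %d (%.2f%%)", sum(phen$children$flagged),
      nrow(phen$children), 100 * mean(phen$children$flagged))

  spells <- stage("spells", link_spells(data$admissions, config$method_codes))
  say("spells: %d from %d admissions", nrow(spells), nrow(data$admissions))
  ptime <- stage("person_time", compute_person_time(cohort, spells))

  incidence <- stage("incidence", cumulative_incidence(cohort, phen))
  rates <- stage("rates", admission_rates(cohort, spells, ptime, phen,
                                          numerator = config$numerator))
  mortality <- stage("mortality", mortality_summary(cohort, phen))
  birth_len <- stage("birth_admission", birth_admission_length(cohort, spells,
                                                               phen))

  history <- stage("sen_history", sen_history(cohort, data$school))
  sen_ever <- stage("sen_ever", sen_ever_summary(cohort, history, phen))
  sen_year <- stage("sen_by_year", sen_by_year(cohort, data$school, phen))
  concord <- stage("concordance", sen_concordance(cohort, history, phen))

  chars <- stage("characteristics",
                 characteristics_table(cohort, phen, data$patients))
  chars_sup <- stage("suppression",
                     apply_suppression(chars, config$suppression_threshold,
                                       config$suppression_token))

  out <- structure(list(
    cohort = cohort, phenotype = phen, spells = spells, person_time = ptime,
    cumulative_incidence = incidence, rates = rates, mortality = mortality,
    birth_admission = birth_len, sen_history = history,
    sen_summary = sen_ever, sen_by_year = sen_year, concordance = concord,
    characteristics = chars, characteristics_suppressed = chars_sup,
    log = log, config = config), class = "neuro_run")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(obj, name) {
      df <- as.data.frame(obj)
      for (j in names(df)) if (inherits(df[[j]], "Date"))
        df[[j]] <- format(df[[j]], "%Y-%m-%d")
      write.csv(df, file.path(config$output_dir, paste0(name, ".csv")),
                row.names = FALSE, na = "")
    }
    wr(cohort, "cohort")
    wr(phen$children, "phenotype")
    wr(phen$subgroups, "phenotype_subgroups")
    wr(spells, "spells")
    wr(ptime, "person_time")
    wr(incidence, "cumulative_incidence")
    wr(rates, "rates")
    wr(mortality, "mortality")
    wr(birth_len, "birth_admission")
    wr(history, "sen_history")
    wr(sen_ever, "sen_summary")
    wr(sen_year, "sen_by_year")
    wr(concord, "concordance")
    wr(chars_sup, "characteristics")
    writeLines(log, file.path(config$output_dir, "run.log"))
  }
  out
}

#' @export
print.neuro_run <- function(x, ...) {
  cat("<neuro_run>\n")
  for (line in x$log) cat(" ", line, "\n")
  inc <- x$cumulative_incidence
  cat(sprintf("  cumulative incidence: %s\n",
              paste(sprintf("<%d: %.1f%%", inc$age_threshold, inc$pct),
                    collapse = ", ")))
  invisible(x)
}
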