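# Synthetic linked records: patients, hospital admissions, deaths, school
# census. The generator emulates the statistical structure the downstream
# analysis assumes (code-list-positive children carry qualifying codes,
# admission counts are Poisson in person-time, transfers create same-day
# contiguous admissions, SEN levels are status-conditional) so the whole
# pipeline is testable without access-controlled administrative data.

# diagnosis fillers: common paediatric codes outside the neurodisability list
.np_filler_dx <- c("J069", "A099", "R509", "K529", "J459", "S934", "L209",
                   "H669", "J219", "R104", "B349", "K409", "N390", "R062")
.np_birth_dx <- "Z380"  # singleton liveborn

.np_bands <- c("under1", "one_to_four", "five_to_ten")

# school-recorded primary-need vocabulary
.np_needs <- c("speech-language-communication", "moderate learning difficulty",
               "learning disability", "physical disability", "visual impairment",
               "hearing impairment", "autistic spectrum disorder", "other")
.np_need_baseline <- setNames(c(0.35, 0.30, 0.04, 0.05, 0.02, 0.02, 0.07, 0.15),
                              .np_needs)

# hospital subgroup -> school-recorded primary need (used for concordance)
.np_subgroup_need_map <- c(
  "autistic spectrum disorders" = "autistic spectrum disorder",
  "learning disability"         = "learning disability",
  "chromosomal anomalies"       = "learning disability",
  "developmental disorders"     = "speech-language-communication",
  "cerebral palsy"              = "physical disability",
  "congenital CNS anomalies"    = "physical disability",
  "neuromuscular disorders"     = "physical disability",
  "degenerative CNS disorders"  = "physical disability",
  "movement disorders"          = "physical disability",
  "hearing impairment"          = "hearing impairment",
  "cochlear implant"            = "hearing impairment",
  "bilateral visual impairment" = "visual impairment",
  "high-risk eye conditions"    = "visual impairment"
)

#' Default subgroup prevalence for the synthetic generator
#'
#' Per-subgroup probabilities of carrying each neurodisability subgroup,
#' drawn independently (comorbidity arises as independent co-occurrence).
#' Magnitudes echo a national birth cohort: developmental disorders,
#' autism and epilepsy are the most common, perinatal brain damage leads
#' the perinatal group, and the implied any-subgroup prevalence
#' (`1 - prod(1 - p)`) is about 0.036.
#'
#' @return named numeric vector of probabilities.
#' @export
default_subgroup_prevalence <- function() {
  c("developmental disorders"       = 0.0060,
    "autistic spectrum disorders"   = 0.0045,
    "epilepsy"                      = 0.0045,
    "hyperkinetic disorders"        = 0.0022,
    "learning disability"           = 0.0015,
    "conduct disorders"             = 0.0005,
    "tic disorders"                 = 0.0003,
    "cerebral palsy"                = 0.0020,
    "chromosomal anomalies"         = 0.0012,
    "sex chromosome anomalies"      = 0.0002,
    "congenital CNS anomalies"      = 0.0025,
    "congenital hypothyroidism"     = 0.0003,
    "foetal alcohol syndrome"       = 0.0001,
    "inherited metabolic conditions" = 0.0005,
    "phakomatoses"                  = 0.0003,
    "other high-risk congenital anomalies" = 0.0005,
    "hydrocephalus"                 = 0.0008,
    "paediatric stroke"             = 0.0003,
    "CNS tumours"                   = 0.0005,
    "inflammatory brain conditions" = 0.0008,
    "bilateral visual impairment"   = 0.0005,
    "high-risk eye conditions"      = 0.0004,
    "hearing impairment"            = 0.0012,
    "cochlear implant"              = 0.0002,
    "degenerative CNS disorders"    = 0.0003,
    "neuromuscular disorders"       = 0.0005,
    "movement disorders"            = 0.0004,
    "severe birth asphyxia"         = 0.0008,
    "perinatal brain damage"        = 0.0020,
    "neonatal abstinence syndrome"  = 0.0004,
    "congenital infections"         = 0.0002,
    "extreme prematurity"           = 0.0010,
    "extremely low birth weight"    = 0.0006)
}

#' Configuration for the synthetic-data generator
#'
#' All rates and probabilities that shape the generated cohort. Defaults
#' describe the study conditions of a national English birth cohort
#' followed to age 11: six birth years from September 2003, any-subgroup
#' prevalence near 3.6%, two thirds of first records before age 5,
#' planned/unplanned admission rate multipliers of 10 and 4.8 for affected
#' children over baseline band rates, death risk 6.1% vs 0.3% by 11, and
#' SEN provision probabilities implying ever-EHCP 39.5% vs 2.4% and
#' ever-support 55.2% vs 29.8% in the school cohort.
#'
#' @param n_children number of children to generate.
#' @param seed integer RNG seed; generation is deterministic given the
#'   seed and configuration.
#' @param birth_window `Date` vector of length 2, inclusive bounds of
#'   birth dates.
#' @param subgroup_prevalence named probabilities per code-list subgroup;
#'   subgroups are drawn independently per child.
#' @param age_at_first_weights two weights (`under5`, `five_to_ten`) for
#'   the age band of a child's first qualifying record; perinatal-category
#'   subgroups are always dated at birth.
#' @param admission_rate_baseline list with `planned` and `unplanned`
#'   per-age-band rates per 100 person-years for unaffected children.
#' @param admission_rate_multiplier rate ratios (`planned`, `unplanned`)
#'   applied for children with any subgroup.
#' @param mortality_risk probability of death before the 11th birthday by
#'   status (`none`, `phenotype`).
#' @param mortality_age_weights per-status weights over age-at-death bands
#'   `<1`, `1-4`, `5-10`.
#' @param p_death_cause_only among affected children who die, probability
#'   that the only qualifying evidence is the death record.
#' @param p_cause_code_on_death probability an affected child's death
#'   record carries a subgroup code as contributory cause.
#' @param birth_los_mean,admission_los_mean geometric mean length of stay
#'   in days by status, for birth and later admissions.
#' @param p_transfer probability an admission is followed by a same-day
#'   transfer admission (exercises spell linkage).
#' @param p_school_linked probability a child has any linked school record.
#' @param p_enrolled per-year-group enrolment probability given linkage and
#'   being alive at the year start (names `R`, `1`..`6`).
#' @param sen_probability per-status vector `ehcp`, `support_given_ehcp`,
#'   `support_given_no_ehcp`: ever-EHCP probability and conditional
#'   ever-support probabilities.
#' @param concordance_prob probability that an affected child with a
#'   mapped hospital subgroup receives the corresponding school-recorded
#'   primary need.
#' @param missingness per-field missing-value probabilities (`sex`,
#'   `gestational_age`, `birthweight`, `maternal_age`).
#' @param admission_method_codes admission-method vocabulary by class.
#' @param codelist `neuro_codelist` from which qualifying codes are drawn.
#' @return a validated list of class `neuro_generator_config`.
#' @export
generator_config <- function(
    n_children = 1000L,
    seed = 20030901L,
    birth_window = as.Date(c("2003-09-01", "2009-08-31")),
    subgroup_prevalence = default_subgroup_prevalence(),
    age_at_first_weights = c(under5 = 2 / 3, five_to_ten = 1 / 3),
    admission_rate_baseline = list(
      planned   = c(under1 = 3.66, one_to_four = 3.67, five_to_ten = 3.21),
      unplanned = c(under1 = 23.39, one_to_four = 7.74, five_to_ten = 2.82)),
    admission_rate_multiplier = c(planned = 10, unplanned = 4.8),
    mortality_risk = c(none = 0.003, phenotype = 0.061),
    mortality_age_weights = list(
      none      = c(under1 = 9711, one_to_four = 1131, five_to_ten = 432) / 11274,
      phenotype = c(under1 = 5475, one_to_four = 1347, five_to_ten = 947) / 7769),
    p_death_cause_only = 0.02,
    p_cause_code_on_death = 0.8,
    birth_los_mean = c(none = 1.5, phenotype = 3),
    admission_los_mean = c(none = 1.5, phenotype = 2.5),
    p_transfer = 0.05,
    p_school_linked = 0.85,
    p_enrolled = c(R = 0.94, `1` = 0.98, `2` = 0.97, `3` = 0.97,
                   `4` = 0.97, `5` = 0.97, `6` = 0.97),
    sen_probability = list(
      none      = c(ehcp = 0.024, support_given_ehcp = 0.79,
                    support_given_no_ehcp = 0.286),
      phenotype = c(ehcp = 0.395, support_given_ehcp = 0.486,
                    support_given_no_ehcp = 0.595)),
    concordance_prob = 0.7,
    missingness = c(sex = 0.003, gestational_age = 0.306,
                    birthweight = 0.215, maternal_age = 0.033),
    admission_method_codes = list(
      elective = c("11", "12", "13"),
      emergency = c("21", "22", "23", "24", "25", "2A", "2B"),
      birth = "82", transfer = "81"),
    codelist = example_codelist()) {
  cfg <- mget(names(formals()))
  probs <- c(cfg$subgroup_prevalence, cfg$age_at_first_weights,
             cfg$mortality_risk, unlist(cfg$mortality_age_weights),
             cfg$p_death_cause_only, cfg$p_cause_code_on_death,
             cfg$p_transfer, cfg$p_school_linked, cfg$p_enrolled,
             unlist(cfg$sen_probability), cfg$concordance_prob,
             cfg$missingness)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  rates <- c(unlist(cfg$admission_rate_baseline), cfg$admission_rate_multiplier,
             cfg$birth_los_mean, cfg$admission_los_mean)
  if (any(rates < 0)) stop("rates and mean lengths of stay must be >= 0")
  if (!inherits(cfg$birth_window, "Date") || length(cfg$birth_window) != 2L ||
      cfg$birth_window[1] >= cfg$birth_window[2])
    stop("birth_window must be two Dates with start < end")
  stopifnot(inherits(cfg$codelist, "neuro_codelist"))
  unknown <- setdiff(names(cfg$subgroup_prevalence), unique(cfg$codelist$subgroup))
  if (length(unknown))
    stop("subgroup_prevalence names not in codelist: ",
         paste(unknown, collapse = ", "))
  cfg$n_children <- as.integer(cfg$n_children)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "neuro_generator_config")
}

#' Any-subgroup prevalence implied by a generator configuration
#'
#' Under independent subgroup draws, `1 - prod(1 - p_k)`.
#'
#' @param config a `neuro_generator_config`.
#' @return a probability.
#' @export
implied_any_prevalence <- function(config) {
  1 - prod(1 - config$subgroup_prevalence)
}

#' Ever-SEN marginal probabilities implied by a generator configuration
#'
#' Converts the conditional parameterisation (`ehcp`,
#' `support_given_ehcp`, `support_given_no_ehcp`) into the marginal
#' probabilities the pipeline estimates: ever-EHCP, ever-support and any
#' provision, per status.
#'
#' @param config a `neuro_generator_config`.
#' @return matrix with rows `none`/`phenotype` and columns
#'   `ever_ehcp`, `ever_support`, `any_provision`.
#' @export
implied_sen_marginals <- function(config) {
  t(vapply(config$sen_probability, function(p) {
    ehcp <- p[["ehcp"]]
    supp <- ehcp * p[["support_given_ehcp"]] +
      (1 - ehcp) * p[["support_given_no_ehcp"]]
    any <- ehcp + (1 - ehcp) * p[["support_given_no_ehcp"]]
    c(ever_ehcp = ehcp, ever_support = supp, any_provision = any)
  }, numeric(3)))
}

#' Cross-record concordance implied by a generator configuration
#'
#' A school need is only observable for children who ever receive SEN
#' provision, so the concordance the pipeline measures for a mapped
#' hospital subgroup is the any-provision probability times the
#' probability the recorded need is the mapped one (the concordance draw,
#' plus the chance the baseline need distribution lands on it anyway).
#'
#' @param config a `neuro_generator_config`.
#' @param subgroup a hospital subgroup with a mapped school need.
#' @return the expected measured proportion.
#' @export
implied_concordance <- function(config, subgroup = "autistic spectrum disorders") {
  need <- .np_subgroup_need_map[[subgroup]]
  if (is.null(need)) stop("no school need mapped for subgroup: ", subgroup)
  p_any <- implied_sen_marginals(config)["phenotype", "any_provision"]
  cp <- config$concordance_prob
  unname(p_any * (cp + (1 - cp) * .np_need_baseline[[need]]))
}

# geometric lengths of stay (days, >= 0) with given mean
.np_rgeom_mean <- function(n, mean) {
  if (n == 0L) return(integer(0))
  if (mean <= 0) return(rep(0L, n))
  rgeom(n, prob = 1 / (1 + mean))
}

# draw an observable code for a code-list entry: extend 3-char prefix
# entries with a random final digit, as hospital data record 4-char codes
.np_observable_code <- function(entries_idx, codelist) {
  e <- codelist[entries_idx, , drop = FALSE]
  code <- e$code
  extend <- e$match_mode == "prefix" & nchar(code) == 3L
  code[extend] <- paste0(code[extend],
                         sample(0:9, sum(extend), replace = TRUE))
  code
}

#' Generate a linked synthetic cohort
#'
#' Produces four linked tables — `patients`, `admissions`, `deaths`,
#' `school` — plus the generator's ground truth, deterministically for a
#' fixed configuration and seed. Every code-list-positive child carries at
#' least one admission or death record with a qualifying code; admission
#' counts are Poisson in each child's alive person-time per age band;
#' same-day transfer admissions are injected to exercise spell linkage;
#' school enrolment, SEN levels and primary needs follow the configured
#' status-conditional probabilities. Children with a perinatal-category
#' subgroup have consistent birth characteristics (gestational age < 27
#' weeks for extreme prematurity, birthweight < 1000 g for extremely low
#' birth weight) and are dated at birth.
#'
#' @param config a [generator_config()].
#' @return a list of class `neuro_synth` with elements `patients`,
#'   `admissions`, `deaths`, `school`, `truth` (per-child assigned status,
#'   subgroups and SEN draws) and `config`.
#' @export
generate_cohort_data <- function(config = generator_config()) {
  stopifnot(inherits(config, "neuro_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n_children
  cl <- config$codelist
  prev <- config$subgroup_prevalence
  subgroups <- names(prev)
  peri <- subgroups[subgroups %in% cl$subgroup[cl$category == "perinatal"]]

  ## -- patients ------------------------------------------------------------
  pid <- sprintf("P%06d", seq_len(n))
  span <- as.integer(config$birth_window[2] - config$birth_window[1])
  birth <- config$birth_window[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  bday11 <- add_years(birth, 11L)

  flags <- matrix(FALSE, n, length(subgroups), dimnames = list(NULL, subgroups))
  for (k in subgroups) flags[, k] <- runif(n) < prev[[k]]
  pheno <- rowSums(flags) > 0L
  status <- ifelse(pheno, "phenotype", "none")

  sex <- ifelse(runif(n) < ifelse(pheno, 0.617, 0.505), "male", "female")

  is_xprem <- if ("extreme prematurity" %in% subgroups)
    flags[, "extreme prematurity"] else rep(FALSE, n)
  is_elbw <- if ("extremely low birth weight" %in% subgroups)
    flags[, "extremely low birth weight"] else rep(FALSE, n)
  gest <- integer(n)
  gest[is_xprem] <- sample(23:26, sum(is_xprem), replace = TRUE)
  npre <- sum(!is_xprem & pheno)
  gest[!is_xprem & pheno] <- sample(27:42, npre, replace = TRUE,
    prob = c(rep(0.012, 5), rep(0.018, 5), rep(0.12, 4), 0.15, 0.10))
  nn <- sum(!is_xprem & !pheno)
  gest[!is_xprem & !pheno] <- sample(27:42, nn, replace = TRUE,
    prob = c(rep(0.001, 5), rep(0.010, 5), rep(0.17, 4), 0.16, 0.085))
  bw <- integer(n)
  bw[is_elbw] <- sample(450:999, sum(is_elbw), replace = TRUE)
  rest <- !is_elbw
  mu <- c(1300, 2600, 3400, 3550)[findInterval(gest[rest], c(0, 32, 37, 41))]
  bw[rest] <- pmax(1000L, as.integer(round(mu + stats::rnorm(sum(rest), 0, 450))))
  mab_levels <- c("<20", "20-24", "25-29", "30-34", "35-39", ">=40")
  mab <- ifelse(pheno,
    sample(mab_levels, n, replace = TRUE, prob = c(.081, .207, .242, .229, .143, .098)),
    sample(mab_levels, n, replace = TRUE, prob = c(.064, .184, .252, .271, .154, .075)))

  miss <- config$missingness
  sex[runif(n) < miss[["sex"]]] <- NA
  gest[runif(n) < miss[["gestational_age"]]] <- NA
  bw[runif(n) < miss[["birthweight"]]] <- NA
  mab[runif(n) < miss[["maternal_age"]]] <- NA
  # a missing gestational field must not hide the extreme-prematurity
  # evidence entirely: those children also carry a P07 code at birth

  patients <- data.table(patient_id = pid, birth_date = birth, sex = sex,
                         gestational_age_weeks = gest, birthweight_g = bw,
                         maternal_age_band = mab)

  ## -- deaths --------------------------------------------------------------
  dies <- runif(n) < config$mortality_risk[status]
  death_date <- rep(as.Date(NA), n)
  if (any(dies)) {
    for (st in c("none", "phenotype")) {
      idx <- which(dies & status == st)
      if (!length(idx)) next
      band <- sample(.np_bands, length(idx), replace = TRUE,
                     prob = config$mortality_age_weights[[st]])
      lo <- fifelse(band == "under1", birth[idx],
            fifelse(band == "one_to_four", add_years(birth[idx], 1L),
                    add_years(birth[idx], 5L)))
      hi <- fifelse(band == "under1", add_years(birth[idx], 1L),
            fifelse(band == "one_to_four", add_years(birth[idx], 5L),
                    bday11[idx]))
      death_date[idx] <- lo + floor(runif(length(idx)) * as.numeric(hi - lo))
    }
  }
  fup_end <- pmin(bday11, death_date, na.rm = TRUE)

  ## -- first-record dates per (child, subgroup) ----------------------------
  ev <- as.data.table(which(flags, arr.ind = TRUE))
  setnames(ev, c("row", "col"), c("i", "k"))
  if (!nrow(ev))
    ev <- data.table(i = integer(0), k = integer(0))
  ev[, subgroup := subgroups[k]]
  ev[, `:=`(birth = birth[i], bday5 = add_years(birth[i], 5L),
            bday11 = bday11[i], death = death_date[i], fup = fup_end[i])]
  # child-level age-at-first band. Perinatal subgroups are dated at birth
  # (forcing those children under 5), so non-perinatal children draw the
  # 5-10 band with an inflated probability that keeps the marginal split
  # of first records at the configured weights
  peri_pos <- rowSums(flags[, colnames(flags) %in% peri, drop = FALSE]) > 0
  p_any <- 1 - prod(1 - prev)
  q_peri <- if (p_any > 0)
    (1 - prod(1 - prev[names(prev) %in% peri])) / p_any else 0
  w510 <- min(1, config$age_at_first_weights[["five_to_ten"]] / (1 - q_peri))
  child_band <- ifelse(peri_pos, "under5",
                       ifelse(runif(n) < w510, "five_to_ten", "under5"))
  ev[, band := child_band[i]]
  ev[subgroup %in% peri, band := "under5"]
  ev[, lo := fifelse(band == "under5", birth, bday5)]
  ev[, hi := fifelse(band == "under5", bday5, bday11)]
  ev[subgroup %in% peri, hi := lo + 1L]  # at birth
  ev[, hi := pmin(hi, fup)]
  ev[lo >= hi, lo := pmax(birth, hi - 1L)]   # died before band start: date at death
  ev[, target := lo + floor(runif(.N) * as.numeric(hi - lo))]
  ev[, target := pmax(birth, pmin(target, fup - 1L, na.rm = TRUE))]
  ev[is.na(target) | target < birth, target := birth]
  # evidence carried only on the death record, for some who die
  death_only <- dies & pheno & (runif(n) < config$p_death_cause_only)
  ev[, via_death_only := death_only[i]]
  ev[via_death_only == TRUE, target := death]
  # draw an observable code per event; death-only evidence must be ICD-10
  # (causes of death carry no procedure codes)
  cl_dt <- as.data.table(cl)[, row := .I]
  ev[, entry := integer(.N)]
  if (nrow(ev)) {
    ev[, entry := {
      rows <- cl_dt[subgroup == .BY[[1]], row]
      rows[sample.int(length(rows), .N, replace = TRUE)]
    }, by = subgroup]
    ev[via_death_only == TRUE & cl$system[entry] == "OPCS4", entry := {
      vapply(subgroup, function(s) {
        rows <- cl_dt[subgroup == s & system == "ICD10", row]
        rows[sample.int(length(rows), 1L)]
      }, integer(1))
    }]
  }
  ev[, code := .np_observable_code(entry, cl)]
  ev[, code_system := cl$system[entry]]

  ## -- admissions ----------------------------------------------------------
  # birth admissions keep the newborn at least overnight; the excess over
  # one day is geometric, so mean length of stay equals the configured mean
  mlos <- config$birth_los_mean
  los_b <- integer(n)
  los_b[pheno] <- 1L + .np_rgeom_mean(sum(pheno), mlos[["phenotype"]] - 1)
  los_b[!pheno] <- 1L + .np_rgeom_mean(sum(!pheno), mlos[["none"]] - 1)
  adm <- list(data.table(
    i = seq_len(n), admission_date = birth,
    discharge_date = birth + los_b,
    admission_method_code = config$admission_method_codes$birth,
    class = "birth", dx = .np_birth_dx, proc = "", is_birth_admission = TRUE))

  mult <- config$admission_rate_multiplier
  alos <- config$admission_los_mean
  band_lo <- list(under1 = birth, one_to_four = add_years(birth, 1L),
                  five_to_ten = add_years(birth, 5L))
  band_hi <- list(under1 = add_years(birth, 1L),
                  one_to_four = add_years(birth, 5L), five_to_ten = bday11)
  for (type in c("planned", "unplanned")) {
    base <- config$admission_rate_baseline[[type]]
    m <- ifelse(pheno, mult[[type]], 1)
    for (b in .np_bands) {
      expo <- pmax(0, as.numeric(pmin(band_hi[[b]], fup_end) - band_lo[[b]]))
      lam <- base[[b]] * m / 100 * expo / 365.25
      nadm <- rpois(n, lam)
      tot <- sum(nadm)
      if (!tot) next
      i <- rep(seq_len(n), nadm)
      off <- floor(runif(tot) * rep(expo, nadm))
      d <- rep(band_lo[[b]], nadm) + off
      los <- integer(tot)
      ph_i <- pheno[i]
      los[ph_i] <- .np_rgeom_mean(sum(ph_i), alos[["phenotype"]])
      los[!ph_i] <- .np_rgeom_mean(sum(!ph_i), alos[["none"]])
      meth <- if (type == "planned")
        sample(config$admission_method_codes$elective, tot, replace = TRUE)
      else sample(config$admission_method_codes$emergency, tot, replace = TRUE)
      adm[[length(adm) + 1L]] <- data.table(
        i = i, admission_date = d, discharge_date = d + los,
        admission_method_code = meth, class = type,
        dx = sample(.np_filler_dx, tot, replace = TRUE), proc = "",
        is_birth_admission = FALSE)
    }
  }
  admdt <- rbindlist(adm)

  ## attach qualifying codes to admissions (or create one when none fits)
  ev_adm <- ev[via_death_only == FALSE]
  if (nrow(ev_adm)) {
    ev_adm[, side := fifelse(target < bday5, "under5", "five_to_ten")]
    admdt[, side := fifelse(admission_date < add_years(birth[i], 5L),
                            "under5", "five_to_ten")]
    admdt[, aid := .I]
    setkey(admdt, i, side, admission_date)
    hit <- admdt[ev_adm, on = .(i, side, admission_date = target),
                 roll = "nearest", mult = "first",
                 .(i, side, ev_row = seq_len(nrow(ev_adm)), aid = x.aid,
                   code = i.code, code_system = i.code_system,
                   target = i.target)]
    # perinatal evidence goes on the birth admission when dated at birth
    found <- hit[!is.na(aid)]
    if (nrow(found)) {
      add_dx <- found[code_system == "ICD10",
                      .(extra = paste(code, collapse = ";")), by = aid]
      add_pr <- found[code_system == "OPCS4",
                      .(extra = paste(code, collapse = ";")), by = aid]
      if (nrow(add_dx))
        admdt[add_dx, on = "aid", dx := paste(dx, i.extra, sep = ";")]
      if (nrow(add_pr))
        admdt[add_pr, on = "aid",
              proc := fifelse(proc == "", i.extra, paste(proc, i.extra, sep = ";"))]
    }
    lost <- hit[is.na(aid)]
    if (nrow(lost)) {
      los <- .np_rgeom_mean(nrow(lost), alos[["phenotype"]])
      admdt <- rbind(admdt[, !"aid"], data.table(
        i = lost$i, admission_date = lost$target,
        discharge_date = lost$target + los,
        admission_method_code = sample(config$admission_method_codes$emergency,
                                       nrow(lost), replace = TRUE),
        class = "unplanned",
        dx = fifelse(lost$code_system == "ICD10",
                     paste(sample(.np_filler_dx, nrow(lost), replace = TRUE),
                           lost$code, sep = ";"),
                     sample(.np_filler_dx, nrow(lost), replace = TRUE)),
        proc = fifelse(lost$code_system == "OPCS4", lost$code, ""),
        is_birth_admission = FALSE, side = NA_character_))
    } else admdt[, aid := NULL]
    admdt[, side := NULL]
  }

  ## a child cannot be newly admitted while still in hospital: truncate each
  ## stay at the next admission date, so index admissions map one-to-one
  ## onto spells and the injected transfers below are the only deliberate
  ## same-day contiguities
  setorder(admdt, i, admission_date, -is_birth_admission)
  admdt[, nxt := shift(admission_date, type = "lead"), by = i]
  admdt[!is.na(nxt) & nxt > admission_date & discharge_date >= nxt,
        discharge_date := nxt - 1L]
  admdt[, nxt := NULL]

  ## same-day transfer continuations
  cand <- admdt[is_birth_admission == FALSE &
                  (is.na(death_date[i]) | discharge_date < death_date[i])]
  take <- runif(nrow(cand)) < config$p_transfer
  if (any(take)) {
    tr <- cand[take]
    los <- .np_rgeom_mean(nrow(tr), 2)
    admdt <- rbind(admdt, data.table(
      i = tr$i, admission_date = tr$discharge_date,
      discharge_date = tr$discharge_date + los,
      admission_method_code = config$admission_method_codes$transfer,
      class = "transfer",
      dx = sample(.np_filler_dx, nrow(tr), replace = TRUE), proc = "",
      is_birth_admission = FALSE))
  }

  ## clip discharges at death; flag in-hospital deaths
  admdt[, death := death_date[i]]
  admdt[, died_in_hospital := !is.na(death) & discharge_date >= death &
          admission_date <= death]
  admdt[died_in_hospital == TRUE, discharge_date := death]
  admdt[, death := NULL]
  setorder(admdt, i, admission_date, discharge_date)
  admissions <- admdt[, .(
    admission_id = sprintf("A%07d", .I), patient_id = pid[i],
    admission_date, discharge_date, admission_method_code,
    diagnosis_codes = dx, procedure_codes = proc,
    is_birth_admission, died_in_hospital)]

  ## -- deaths table --------------------------------------------------------
  didx <- which(dies)
  deaths <- data.table(patient_id = pid[didx], death_date = death_date[didx])
  if (nrow(deaths)) {
    # underlying causes outside the code list (matching ones are appended
    # separately below for affected children)
    underlying <- sample(c("R99X", "J189", "C911", "Q249", "P285"),
                         nrow(deaths), replace = TRUE)
    carry <- death_only[didx] |
      (pheno[didx] & runif(length(didx)) < config$p_cause_code_on_death)
    extra <- ev[i %in% didx[carry] & code_system == "ICD10",
                .(codes = paste(unique(code), collapse = ";")), by = i]
    cause <- data.table(i = didx, cause = underlying)
    cause[extra, on = "i", cause := paste(cause, i.codes, sep = ";")]
    deaths[, cause_codes := cause$cause]
  } else deaths[, cause_codes := character(0)]

  ## -- school records ------------------------------------------------------
  linked <- runif(n) < config$p_school_linked
  yg <- c("R", "1", "2", "3", "4", "5", "6")
  ay0 <- academic_year_start(birth)
  sch <- rbindlist(lapply(seq_along(yg), function(g) {
    ystart <- as.Date(sprintf("%d-09-01", ay0 + 4L + g))  # R starts Y+5
    alive <- is.na(death_date) | death_date > ystart
    enr <- linked & alive & runif(n) < config$p_enrolled[[yg[g]]]
    data.table(i = which(enr), year_group = yg[g],
               ay = ay0[enr] + 4L + g)
  }))
  setorder(sch, i, ay)

  sen_p <- config$sen_probability
  p_e <- unname(vapply(sen_p, `[[`, numeric(1), "ehcp"))[match(status, names(sen_p))]
  ever_ehcp <- runif(n) < p_e
  p_s <- fifelse(ever_ehcp,
    vapply(sen_p, `[[`, numeric(1), "support_given_ehcp")[match(status, names(sen_p))],
    vapply(sen_p, `[[`, numeric(1), "support_given_no_ehcp")[match(status, names(sen_p))])
  ever_support <- runif(n) < p_s

  # child-level primary need (recorded in every SEN year)
  need <- sample(.np_needs, n, replace = TRUE, prob = .np_need_baseline)
  mapped <- .np_subgroup_need_map
  ev_map <- if (nrow(ev))
    ev[subgroup %in% names(mapped),
       .(need = unname(mapped[subgroup[sample.int(.N, 1L)]])), by = i]
  else ev[, .(i, need = character(0))]
  if (nrow(ev_map)) {
    use <- runif(nrow(ev_map)) < config$concordance_prob
    need[ev_map$i[use]] <- ev_map$need[use]
  }

  sch[, `:=`(sen_level = "none", primary_need = "none")]
  if (nrow(sch)) {
    sch[, ord := seq_len(.N), by = i]
    sch[, nyr := .N, by = i]
    pick <- sch[, .(nyr = .N), by = i]
    pick[, `:=`(e = ever_ehcp[i], s = ever_support[i])]
    pick[, onset := ceiling(runif(.N) * nyr)]
    # a child with both support and an EHCP needs a year before EHCP onset
    pick[e & s & onset == 1L & nyr > 1L, onset := 2L]
    sch[pick, on = "i", `:=`(e = i.e, s = i.s, onset = i.onset)]
    sch[e == TRUE & ord >= onset, sen_level := "ehcp"]
    sch[e == TRUE & s == TRUE & ord < onset, sen_level := "support"]
    sch[e == FALSE & s == TRUE & ord >= onset, sen_level := "support"]
    sch[sen_level != "none", primary_need := need[i]]
  }
  school <- sch[, .(patient_id = pid[i], academic_year = academic_year_label(ay),
                    year_group, sen_level, primary_need)]

  truth <- data.table(
    patient_id = pid, phenotype = pheno,
    subgroups = vapply(seq_len(n), function(j)
      paste(subgroups[flags[j, ]], collapse = ";"), character(1)),
    first_band = ifelse(pheno, child_band, NA_character_),
    school_linked = linked, ever_support = ever_support,
    ever_ehcp = ever_ehcp, died = dies)
  truth[phenotype & peri_pos, first_band := "under5"]

  structure(list(patients = setDF(patients), admissions = setDF(admissions),
                 deaths = setDF(deaths), school = setDF(school),
                 truth = setDF(truth), config = config),
            class = "neuro_synth")
}

#' @export
print.neuro_synth <- function(x, ...) {
  cat(sprintf(paste0("<neuro_synth> %d children (seed %d): %d admissions, ",
                     "%d deaths, %d school-year records; %.1f%% with a ",
                     "neurodisability subgroup\n"),
              nrow(x$patients), x$config$seed, nrow(x$admissions),
              nrow(x$deaths), nrow(x$school),
              100 * mean(x$truth$phenotype)))
  invisible(x)
}

# column types: "na_character" treats an empty string as a missing value;
# plain "character" keeps it (an empty code list is empty, not missing)
.np_schemas <- list(
  patients = c(patient_id = "character", birth_date = "date",
               sex = "na_character",
               gestational_age_weeks = "integer", birthweight_g = "integer",
               maternal_age_band = "na_character"),
  admissions = c(admission_id = "character", patient_id = "character",
                 admission_date = "date", discharge_date = "date",
                 admission_method_code = "character",
                 diagnosis_codes = "character", procedure_codes = "character",
                 is_birth_admission = "logical", died_in_hospital = "logical"),
  deaths = c(patient_id = "character", death_date = "date",
             cause_codes = "character"),
  school = c(patient_id = "character", academic_year = "character",
             year_group = "character", sen_level = "character",
             primary_need = "character")
)

#' Write the four linked tables to CSV
#'
#' `patients.csv`, `admissions.csv`, `deaths.csv`, `school.csv` with
#' ISO-8601 dates and empty strings for missing values. Code lists within
#' a record are semicolon-delimited, position 1 the primary code.
#'
#' @param datasets a `neuro_synth` or a plain list with the four tables.
#' @param dir output directory, created if needed.
#' @return invisibly, the written file paths.
#' @seealso [read_datasets()] for the inverse; round-tripping is identity.
#' @export
write_datasets <- function(datasets, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(.np_schemas)) {
    df <- as.data.frame(datasets[[nm]])
    stopifnot(identical(names(df), names(.np_schemas[[nm]])))
    for (j in names(df)) if (inherits(df[[j]], "Date"))
      df[[j]] <- format(df[[j]], "%Y-%m-%d")
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE, na = "")
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read the four linked tables from a directory
#'
#' Validates each file's header against the expected schema (rejection
#' names the offending column) and restores column types: ISO dates,
#' integers, logicals; empty strings become missing values.
#'
#' @param dir directory containing `patients.csv`, `admissions.csv`,
#'   `deaths.csv`, `school.csv`.
#' @return a list with the four data.frames.
#' @export
read_datasets <- function(dir) {
  out <- list()
  for (nm in names(.np_schemas)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop("missing input file: ", p)
    df <- read.csv(p, colClasses = "character", check.names = TRUE)
    sch <- .np_schemas[[nm]]
    if (!identical(names(df), names(sch))) {
      bad <- c(setdiff(names(sch), names(df)), setdiff(names(df), names(sch)))
      stop(sprintf("%s.csv: unexpected column set (offending: %s)", nm,
                   paste(bad, collapse = ", ")))
    }
    for (j in names(sch)) {
      v <- df[[j]]
      if (sch[[j]] != "character") v[!is.na(v) & v == ""] <- NA
      df[[j]] <- switch(sch[[j]],
        date = as.Date(v),
        integer = suppressWarnings(as.integer(v)),
        logical = v %in% c("TRUE", "true", "1"),
        v)
    }
    out[[nm]] <- df
  }
  out
}
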