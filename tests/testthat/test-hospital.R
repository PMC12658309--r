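test_that("same-day transfers merge into one spell typed by the earliest admission", {
  adm <- make_admissions("a", c("2005-01-01", "2005-01-05"),
                         c("2005-01-05", "2005-01-09"),
                         method = c("11", "21"))
  adm$admission_id <- c("A1", "A2")
  sp <- link_spells(adm)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$start_date, as.Date("2005-01-01"))
  expect_equal(sp$end_date, as.Date("2005-01-09"))
  expect_equal(sp$spell_type, "planned")  # earliest information wins
  expect_equal(sp$admission_ids, "A1;A2")

  # a one-day gap keeps two spells
  adm2 <- make_admissions("a", c("2005-01-01", "2005-01-06"),
                          c("2005-01-05", "2005-01-09"))
  sp2 <- link_spells(adm2)
  expect_equal(nrow(sp2), 2L)

  # nesting merges; plain overlap merges with a warning
  adm3 <- make_admissions("a", c("2005-01-01", "2005-01-02"),
                          c("2005-01-10", "2005-01-03"))
  expect_silent(sp3 <- link_spells(adm3))
  expect_equal(nrow(sp3), 1L)
  adm4 <- make_admissions("a", c("2005-01-01", "2005-01-03"),
                          c("2005-01-05", "2005-01-09"))
  expect_warning(sp4 <- link_spells(adm4), "overlap")
  expect_equal(nrow(sp4), 1L)
  expect_error(link_spells(make_admissions("a", "2005-01-05", "2005-01-01")),
               "discharge before admission")
})

test_that("spell linkage equals the day-set components oracle on random sets", {
  set.seed(99)
  for (rep in 1:500) {
    n <- sample(1:8, 1)
    start <- as.Date("2005-01-01") + sample(0:40, n, replace = TRUE)
    adm <- make_admissions("a", start, start + sample(0:6, n, replace = TRUE))
    adm$admission_id <- sprintf("A%02d", seq_len(n))
    sp <- suppressWarnings(link_spells(adm))
    want <- oracle_spell_ranges(adm)
    expect_equal(nrow(sp), nrow(want))
    expect_equal(as.integer(sp$start_date), want$start)
    expect_equal(as.integer(sp$end_date), want$end)
    # idempotence: re-linking the spells as admissions changes nothing
    again <- suppressWarnings(link_spells(data.frame(
      admission_id = sp$spell_id, patient_id = sp$patient_id,
      admission_date = sp$start_date, discharge_date = sp$end_date,
      admission_method_code = "21", diagnosis_codes = "", procedure_codes = "",
      is_birth_admission = FALSE, died_in_hospital = FALSE)))
    expect_equal(again$start_date, sp$start_date)
    expect_equal(again$end_date, sp$end_date)
    # order invariance
    shuf <- suppressWarnings(link_spells(adm[sample.int(n), , drop = FALSE]))
    expect_equal(shuf$start_date, sp$start_date)
  }
})

test_that("person-time splits at birthdays and excludes hospital days", {
  pts <- make_patients("a", "2004-03-15")
  co <- build_birth_cohort(pts, no_deaths)
  # no admissions: at-risk days equal calendar follow-up
  pt0 <- compute_person_time(
    co, link_spells(make_admissions("a", "2005-01-01", "2005-01-02")[0, ]))
  tot <- pt0[pt0$band == "under11", ]
  expect_equal(tot$days_total,
               as.numeric(as.Date("2015-03-15") - as.Date("2004-03-15")))
  expect_equal(tot$days_at_risk, tot$days_total)

  # one spell spanning the 1st birthday: 10 days before, 5 after
  adm <- make_admissions("a", "2005-03-05", "2005-03-20")
  pt1 <- compute_person_time(co, link_spells(adm))
  expect_equal(pt1$days_in_hospital[pt1$band == "under1"], 10)
  expect_equal(pt1$days_in_hospital[pt1$band == "one_to_four"], 5)

  # death in hospital at age 2 clips both totals and hospital days
  dth <- data.frame(patient_id = "a", death_date = as.Date("2006-04-01"))
  co2 <- build_birth_cohort(pts, dth)
  adm2 <- make_admissions("a", "2006-03-25", "2006-04-01", died = TRUE)
  pt2 <- compute_person_time(co2, link_spells(adm2))
  tot2 <- pt2[pt2$band == "under11", ]
  expect_equal(tot2$days_total,
               as.numeric(as.Date("2006-04-01") - as.Date("2004-03-15")))
  expect_equal(tot2$days_in_hospital, 7)
})

test_that("person-time equals per-day enumeration on random children", {
  set.seed(2718)
  pts <- make_patients(sprintf("c%03d", 1:100),
                       as.Date("2003-09-01") + sample(0:2100, 100, TRUE))
  dth <- data.frame(patient_id = pts$patient_id[1:10],
                    death_date = pts$birth_date[1:10] +
                      sample(30:3500, 10, TRUE))
  co <- build_birth_cohort(pts, dth)
  adm <- do.call(rbind, lapply(seq_len(100), function(j) {
    n <- sample(0:5, 1)
    if (!n) return(NULL)
    start <- pts$birth_date[j] + sample(0:3800, n, TRUE)
    a <- make_admissions(pts$patient_id[j], start,
                         start + sample(0:20, n, TRUE))
    a$admission_id <- sprintf("A%03d_%d", j, seq_len(n))
    a
  }))
  sp <- suppressWarnings(link_spells(adm))
  pt <- compute_person_time(co, sp)
  for (j in sample.int(100, 100)) {
    id <- pts$patient_id[j]
    want <- oracle_person_time(co$birth_date[co$patient_id == id],
                               co$followup_end[co$patient_id == id],
                               sp[sp$patient_id == id, ])
    got <- pt[pt$patient_id == id & pt$band != "under11", ]
    expect_equal(got$days_total, want$days_total)
    expect_equal(got$days_in_hospital, want$days_in_hospital)
  }
  # conservation: bands sum to the aggregate and hospital days never exceed totals
  agg <- aggregate(cbind(days_total, days_in_hospital, days_at_risk) ~ patient_id,
                   data = pt[pt$band != "under11", ], FUN = sum)
  tot <- pt[pt$band == "under11", ]
  tot <- tot[match(agg$patient_id, tot$patient_id), ]
  expect_equal(agg$days_total, tot$days_total)
  expect_equal(agg$days_at_risk, tot$days_at_risk)
  expect_true(all(pt$days_in_hospital <= pt$days_total))
  expect_true(all(pt$days_at_risk >= 0))
})

test_that("cumulative incidence reports both proportions and rates", {
  # 3-child worked fixture with hand-computed person-years
  pts <- make_patients(c("a", "b", "c"), c("2004-01-01", "2004-01-01",
                                           "2004-01-01"))
  dth <- data.frame(patient_id = "c", death_date = as.Date("2006-01-01"))
  cl <- make_codelist(list(list("G40", "ICD10", "epilepsy",
                                "complex neurologic")))
  adm <- make_admissions("a", "2007-01-01", "2007-01-02", dx = "G403")
  co <- build_birth_cohort(pts, dth)
  ph <- phenotype_cohort(co, adm, dth, pts, cl)
  ci <- cumulative_incidence(co, ph, c(1, 5, 11))
  expect_equal(ci$n_cases, c(0L, 1L, 1L))
  expect_equal(ci$proportion, c(0, 1 / 3, 1 / 3))
  # person-years at threshold 5: a contributes to first record (3y),
  # b the full 5 years, c until death (2y) -- all in exact days
  py5 <- as.numeric(as.Date("2007-01-01") - as.Date("2004-01-01")) / 365.25 +
    as.numeric(as.Date("2009-01-01") - as.Date("2004-01-01")) / 365.25 +
    as.numeric(as.Date("2006-01-01") - as.Date("2004-01-01")) / 365.25
  expect_equal(ci$person_years[2], py5)
  expect_equal(ci$rate_per_100py[2], round_half_up(100 / py5, 2))
  # a first record exactly on the threshold birthday is not a case
  adm_b <- make_admissions("b", "2005-01-01", "2005-01-02", dx = "G403")
  ph_b <- phenotype_cohort(co, adm_b, dth, pts, cl)
  expect_equal(cumulative_incidence(co, ph_b, 1)$n_cases, 0L)
  expect_error(cumulative_incidence(co, ph, 12), "11")
})

test_that("admission rates count spells per 100 at-risk person-years", {
  syn <- generate_cohort_data(generator_config(n_children = 4000, seed = 31))
  co <- build_birth_cohort(syn$patients, syn$deaths)
  ph <- phenotype_cohort(co, syn$admissions, syn$deaths, syn$patients,
                         example_codelist())
  sp <- suppressWarnings(link_spells(syn$admissions))
  pt <- compute_person_time(co, sp)
  rt <- admission_rates(co, sp, pt, ph)
  # internal consistency: stored rate and ratio reproduce from stored parts
  ok <- !is.na(rt$rate_per_100py)
  expect_equal(rt$rate_per_100py[ok],
               100 * rt$n_events[ok] / rt$person_years[ok])
  ref <- rt[rt$group == "none", ]
  any_rows <- rt[rt$group == "any", ]
  m <- match(paste(any_rows$spell_type, any_rows$band),
             paste(ref$spell_type, ref$band))
  expect_equal(any_rows$rate_ratio,
               any_rows$rate_per_100py / ref$rate_per_100py[m])
  # birth spells never enter the planned/unplanned numerators
  n_birth <- sum(sp$spell_type == "birth")
  expect_gt(n_birth, 0)
  expect_false("birth" %in% rt$spell_type)
  rt_b <- admission_rates(co, sp, pt, ph, include_birth_spells = TRUE)
  expect_true("birth" %in% rt_b$spell_type)
  # counting raw admissions instead of spells can only increase numerators
  rt_a <- admission_rates(co, sp, pt, ph, numerator = "admissions")
  expect_true(all(rt_a$n_events >= rt$n_events))
  # subgroup grouping keeps the unaffected reference
  rt_s <- admission_rates(co, sp, pt, ph, by = "subgroup")
  expect_true("none" %in% rt_s$group)
  expect_true(any(unique(ph$subgroups$subgroup) %in% rt_s$group))
})

test_that("mortality summary uses group denominators and age-at-death bands", {
  pts <- make_patients(c("a", "b", "c", "d"), "2004-03-15")
  dth <- data.frame(patient_id = c("a", "b"),
                    death_date = as.Date(c("2004-06-01", "2011-08-01")))
  cl <- make_codelist(list(list("G40", "ICD10", "epilepsy",
                                "complex neurologic")))
  adm <- make_admissions(c("a", "b"), "2004-04-01", "2004-04-02", dx = "G403")
  adm$admission_id <- c("A1", "A2")
  co <- build_birth_cohort(pts, dth)
  ph <- phenotype_cohort(co, adm, dth, pts, cl)
  ms <- mortality_summary(co, ph)
  any11 <- ms[ms$group == "any" & ms$band == "under11", ]
  expect_equal(any11$n_group, 2L)
  expect_equal(any11$n_deaths, 2L)
  expect_equal(any11$pct, 100)
  expect_equal(ms$n_deaths[ms$group == "any" & ms$band == "under1"], 1L)
  expect_equal(ms$n_deaths[ms$group == "any" & ms$band == "five_to_ten"], 1L)
  expect_true(all(ms$n_deaths[ms$group == "none"] == 0L))
})

test_that("birth-admission length summarises the birth spell in days", {
  lens <- c(1, 1, 2, 3, 10)
  pts <- make_patients(sprintf("p%d", 1:5), "2004-03-15")
  adm <- make_admissions(pts$patient_id, "2004-03-15",
                         as.character(as.Date("2004-03-15") + lens),
                         method = "82", birth_adm = TRUE)
  adm$admission_id <- sprintf("A%d", 1:5)
  cl <- make_codelist(list(list("G40", "ICD10", "epilepsy",
                                "complex neurologic")))
  co <- build_birth_cohort(pts, no_deaths)
  ph <- phenotype_cohort(co, adm, no_deaths, pts, cl)
  bl <- birth_admission_length(co, link_spells(adm), ph)
  expect_equal(bl$group, "none")
  expect_equal(bl$median, 2)
  expect_equal(bl$q25, 1)
  expect_equal(bl$q75, 3)
  expect_equal(bl$mean, mean(lens))
  # same-day discharge counts as 0 days
  adm0 <- make_admissions("p1", "2004-03-15", "2004-03-15", method = "82",
                          birth_adm = TRUE)
  bl0 <- birth_admission_length(co[co$patient_id == "p1", ],
                                link_spells(adm0), ph)
  expect_equal(bl0$median, 0)
})
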