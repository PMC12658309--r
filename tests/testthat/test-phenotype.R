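mini_codelist <- function() make_codelist(list(
  list("F84", "ICD10", "autism", "neurodevelopmental"),
  list("G40", "ICD10", "epilepsy", "complex neurologic"),
  list("Q05", "ICD10", "CNS congenital anomaly", "inherited/congenital"),
  list("A12", "OPCS4", "hydrocephalus", "high-risk brain"),
  list("P072", "ICD10", "extreme prematurity", "perinatal"),
  list("P070", "ICD10", "extremely low birth weight", "perinatal")))

test_that("qualifying codes in any position flag a child with dated subgroups", {
  cl <- mini_codelist()
  pts <- make_patients("a", "2004-03-15")
  adm <- make_admissions("a", "2007-06-01", "2007-06-02",
                         dx = "J069;F840")  # secondary position
  ph <- phenotype_cohort(build_birth_cohort(pts, no_deaths), adm, no_deaths,
                         pts, cl)
  ch <- ph$children
  expect_true(ch$flagged)
  expect_equal(ch$subgroups, "autism")
  expect_equal(ch$age_band, "under5")
  expect_equal(ch$source, "admission_diagnosis")
  expect_equal(ch$first_record_date, as.Date("2007-06-01"))
})

test_that("first record and per-subgroup dates are minima over events", {
  cl <- mini_codelist()
  pts <- make_patients("a", "2004-03-15")
  adm <- rbind(
    make_admissions("a", "2010-06-01", "2010-06-03", dx = "G403"),  # age 6
    make_admissions("a", "2006-05-10", "2006-05-11", dx = "Q059"))  # age 2
  adm$admission_id <- c("A1", "A2")
  ph <- phenotype_cohort(build_birth_cohort(pts, no_deaths), adm, no_deaths,
                         pts, cl)
  expect_equal(ph$children$first_record_date, as.Date("2006-05-10"))
  expect_equal(ph$children$age_band, "under5")
  expect_setequal(strsplit(ph$children$subgroups, ";")[[1]],
                  c("epilepsy", "CNS congenital anomaly"))
  sg <- ph$subgroups
  expect_equal(sg$first_date[sg$subgroup == "epilepsy"], as.Date("2010-06-01"))
  expect_equal(sg$first_date[sg$subgroup == "CNS congenital anomaly"],
               as.Date("2006-05-10"))
})

test_that("birth characteristics trigger perinatal subgroups at birth", {
  cl <- mini_codelist()
  pts <- make_patients("a", "2004-03-15", gest = 25L)
  ph <- phenotype_cohort(build_birth_cohort(pts, no_deaths),
                         make_admissions("a", "2004-03-15", "2004-03-20",
                                         method = "82", birth_adm = TRUE),
                         no_deaths, pts, cl)
  expect_true(ph$children$flagged)
  expect_equal(ph$children$source, "birth_characteristic")
  expect_equal(ph$children$age_at_first_record_days, 0L)
  expect_equal(ph$children$subgroups, "extreme prematurity")

  # gestational age of exactly 27 weeks, or a missing field, never triggers
  for (g in list(27L, NA_integer_)) {
    pts2 <- make_patients("a", "2004-03-15", gest = g)
    ph2 <- phenotype_cohort(build_birth_cohort(pts2, no_deaths),
                            make_admissions("a", "2004-03-15", "2004-03-16"),
                            no_deaths, pts2, cl)
    expect_false(ph2$children$flagged)
  }
  # birthweight below 1000 g triggers its own subgroup
  pts3 <- make_patients("a", "2004-03-15", bw = 900L)
  ph3 <- phenotype_cohort(build_birth_cohort(pts3, no_deaths),
                          make_admissions("a", "2004-03-15", "2004-03-16"),
                          no_deaths, pts3, cl)
  expect_equal(ph3$children$subgroups, "extremely low birth weight")
})

test_that("a contributory cause of death is qualifying evidence dated at death", {
  cl <- mini_codelist()
  pts <- make_patients("a", "2004-03-15")
  dth <- data.frame(patient_id = "a", death_date = as.Date("2011-07-01"),
                    cause_codes = "J189;G403")
  co <- build_birth_cohort(pts, dth)
  ph <- phenotype_cohort(co, make_admissions("a", "2005-01-01", "2005-01-02"),
                         dth, pts, cl)
  expect_true(ph$children$flagged)
  expect_equal(ph$children$source, "death_cause")
  expect_equal(ph$children$age_band, "five_to_ten")
  expect_equal(ph$children$first_record_date, as.Date("2011-07-01"))

  # the dating switch keeps the flag but removes the date
  ph2 <- phenotype_cohort(co, make_admissions("a", "2005-01-01", "2005-01-02"),
                          dth, pts, cl, death_cause_dating = "exclude")
  expect_true(ph2$children$flagged)
  expect_equal(ph2$children$age_band, "none")
  expect_true(is.na(ph2$children$first_record_date))
})

test_that("events on or after the 11th birthday are out of observation", {
  cl <- mini_codelist()
  pts <- make_patients("a", "2004-03-15")
  adm <- make_admissions("a", "2015-03-15", "2015-03-16", dx = "F840")
  ph <- phenotype_cohort(build_birth_cohort(pts, no_deaths), adm, no_deaths,
                         pts, cl)
  expect_false(ph$children$flagged)
  expect_error(phenotype_cohort(build_birth_cohort(pts, no_deaths),
                                make_admissions("ghost", "2005-01-01",
                                                "2005-01-02"),
                                no_deaths, pts, cl), "unknown patient")
})

test_that("procedure codes flag through the OPCS path", {
  cl <- mini_codelist()
  pts <- make_patients("a", "2004-03-15")
  adm <- make_admissions("a", "2006-01-01", "2006-01-10", proc = "A121")
  ph <- phenotype_cohort(build_birth_cohort(pts, no_deaths), adm, no_deaths,
                         pts, cl)
  expect_true(ph$children$flagged)
  expect_equal(ph$children$source, "admission_procedure")
  expect_equal(ph$children$subgroups, "hydrocephalus")
})

test_that("flagging is monotone in evidence and age threshold", {
  cl <- example_codelist()
  syn <- generate_cohort_data(generator_config(n_children = 3000, seed = 5))
  co <- build_birth_cohort(syn$patients, syn$deaths)
  ph <- phenotype_cohort(co, syn$admissions, syn$deaths, syn$patients, cl)
  ch <- merge(ph$children, co[, c("patient_id", "birth_date")],
              by = "patient_id")
  flagged_by <- function(t) {
    !is.na(ch$first_record_date) &
      ch$first_record_date < add_years(ch$birth_date, t)
  }
  f1 <- flagged_by(1L); f5 <- flagged_by(5L); f11 <- flagged_by(11L)
  expect_true(all(f5[f1]))
  expect_true(all(f11[f5]))
  # under5 and five_to_ten partition the flagged children
  expect_equal(sum(ch$age_band == "under5") + sum(ch$age_band == "five_to_ten"),
               sum(ch$flagged))
  # adding an admission can never unflag a child
  extra <- make_admissions(syn$patients$patient_id[1],
                           syn$patients$birth_date[1] + 30,
                           syn$patients$birth_date[1] + 31)
  ph2 <- phenotype_cohort(co, rbind(syn$admissions, extra), syn$deaths,
                          syn$patients, cl)
  expect_true(all(ph$children$flagged <= ph2$children$flagged[
    match(ph$children$patient_id, ph2$children$patient_id)]))
  # a code list with no matching entries flags nobody (no birth triggers:
  # replace perinatal fields first)
  pts_safe <- syn$patients
  pts_safe$gestational_age_weeks <- pmax(pts_safe$gestational_age_weeks, 30L)
  pts_safe$birthweight_g <- pmax(pts_safe$birthweight_g, 2000L)
  inert <- make_codelist(list(
    list("U07", "ICD10", "epilepsy", "complex neurologic")))
  ph3 <- phenotype_cohort(co, syn$admissions, syn$deaths, pts_safe, inert)
  expect_equal(sum(ph3$children$flagged), 0L)
})
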