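test_that("generation is deterministic for a fixed seed and leaves the RNG alone", {
  cfg <- generator_config(n_children = 300, seed = 123)
  s1 <- generate_cohort_data(cfg)
  set.seed(777)
  before <- .Random.seed
  s2 <- generate_cohort_data(cfg)
  expect_identical(before, .Random.seed)  # caller's RNG state restored
  for (nm in c("patients", "admissions", "deaths", "school", "truth"))
    expect_identical(s1[[nm]], s2[[nm]])
  s3 <- generate_cohort_data(generator_config(n_children = 300, seed = 124))
  expect_false(identical(s1$admissions, s3$admissions))
})

test_that("configuration is validated", {
  expect_error(generator_config(p_transfer = 1.5), "probabilities")
  expect_error(generator_config(admission_rate_multiplier =
                                  c(planned = -1, unplanned = 4.8)), "rates")
  expect_error(generator_config(birth_window =
                                  as.Date(c("2009-08-31", "2003-09-01"))),
               "birth_window")
  expect_error(generator_config(subgroup_prevalence = c(martian = 0.1)),
               "not in codelist")
})

test_that("zero prevalence yields zero phenotyped children end to end", {
  cfg <- generator_config(n_children = 500, seed = 9,
                          subgroup_prevalence =
                            setNames(rep(0, 33), names(default_subgroup_prevalence())))
  syn <- generate_cohort_data(cfg)
  expect_false(any(syn$truth$phenotype))
  co <- build_birth_cohort(syn$patients, syn$deaths)
  ph <- phenotype_cohort(co, syn$admissions, syn$deaths, syn$patients,
                         cfg$codelist)
  expect_equal(sum(ph$children$flagged), 0L)
})

test_that("structural invariants hold: dates, birth admissions, transfers", {
  syn <- generate_cohort_data(generator_config(n_children = 3000, seed = 21))
  adm <- merge(syn$admissions, syn$patients[, c("patient_id", "birth_date")],
               by = "patient_id")
  expect_true(all(adm$admission_date >= adm$birth_date))
  expect_true(all(adm$discharge_date >= adm$admission_date))
  # at most one birth admission per child, dated at birth
  ba <- adm[adm$is_birth_admission, ]
  expect_false(any(duplicated(ba$patient_id)))
  expect_true(all(ba$admission_date == ba$birth_date))
  # no admission after death; at most one death per child
  adm2 <- merge(syn$admissions, syn$deaths[, c("patient_id", "death_date")])
  expect_true(all(adm2$admission_date <= adm2$death_date))
  expect_true(all(adm2$discharge_date <= adm2$death_date))
  expect_false(any(duplicated(syn$deaths$patient_id)))
  # injected transfers start on a prior discharge date of the same child
  tr <- adm[adm$admission_method_code == "81", ]
  expect_gt(nrow(tr), 0)
  key_prior <- paste(adm$patient_id, adm$discharge_date)
  expect_true(all(paste(tr$patient_id, tr$admission_date) %in% key_prior))
  # every phenotype-positive child carries qualifying evidence somewhere
  cfg <- syn$config
  co <- build_birth_cohort(syn$patients, syn$deaths)
  ph <- phenotype_cohort(co, syn$admissions, syn$deaths, syn$patients,
                         cfg$codelist)
  expect_identical(sort(ph$children$patient_id[ph$children$flagged]),
                   sort(syn$truth$patient_id[syn$truth$phenotype]))
  # school records: one per (child, academic year), year group consistent
  # with the September-cutoff rule
  expect_false(any(duplicated(syn$school[, c("patient_id", "academic_year")])))
  y1 <- merge(syn$school[syn$school$year_group == "1", ],
              syn$patients[, c("patient_id", "birth_date")])
  expect_true(all(y1$academic_year ==
                    academic_year_label(academic_year_start(
                      year1_start_date(y1$birth_date)))))
})

test_that("generated prevalence matches the configured binomial draw", {
  cfg <- generator_config(n_children = 20000, seed = 303)
  syn <- generate_cohort_data(cfg)
  p0 <- implied_any_prevalence(cfg)
  se <- sqrt(p0 * (1 - p0) / cfg$n_children)
  expect_lt(abs(mean(syn$truth$phenotype) - p0), 3 * se)
})

test_that("datasets round-trip through CSV including missing values", {
  syn <- generate_cohort_data(generator_config(n_children = 100, seed = 8))
  dir <- tempfile()
  write_datasets(syn, dir)
  back <- read_datasets(dir)
  for (nm in c("patients", "admissions", "deaths", "school"))
    expect_identical(back[[nm]], syn[[nm]], label = nm)
  # empty string reads back as a missing value
  expect_true(any(is.na(back$patients$gestational_age_weeks)))

  # a hand-built admission file parses its ISO dates
  dir2 <- tempfile(); dir.create(dir2)
  file.copy(file.path(dir, c("patients.csv", "deaths.csv", "school.csv")), dir2)
  writeLines(c(
    "admission_id,patient_id,admission_date,discharge_date,admission_method_code,diagnosis_codes,procedure_codes,is_birth_admission,died_in_hospital",
    "A1,P000001,2005-01-01,2005-01-05,21,J069,,FALSE,FALSE",
    "A2,P000001,2005-01-05,2005-01-09,81,J069,,FALSE,FALSE",
    "A3,P000002,2006-03-02,2006-03-02,11,K529,,FALSE,FALSE"),
    file.path(dir2, "admissions.csv"))
  hand <- read_datasets(dir2)
  expect_equal(hand$admissions$admission_date,
               as.Date(c("2005-01-01", "2005-01-05", "2006-03-02")))
  # schema violations are rejected naming the column
  writeLines("admission_id,patient_id,when", file.path(dir2, "admissions.csv"))
  expect_error(read_datasets(dir2), "when")
  expect_error(read_datasets(tempfile()), "missing input file")
})
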