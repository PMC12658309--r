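# Independent brute-force oracles and small fixture builders.

options(neurophen.quiet = TRUE)

# naive scan over every code-list entry (oracle for match_code)
oracle_match <- function(observed, system, codelist) {
  lapply(observed, function(o) {
    hit <- vapply(seq_len(nrow(codelist)), function(j) {
      codelist$system[j] == system &&
        (if (codelist$match_mode[j] == "prefix")
          startsWith(o, codelist$code[j]) else o == codelist$code[j])
    }, logical(1))
    sort(unique(codelist$subgroup[hit]))
  })
}

# day-set connected-components oracle for spell linkage (one patient):
# each admission covers the inclusive day range [admission, discharge];
# admissions sharing at least one day belong to one spell
oracle_spell_ranges <- function(adm) {
  sets <- lapply(seq_len(nrow(adm)), function(j)
    seq(as.integer(adm$admission_date[j]), as.integer(adm$discharge_date[j])))
  comps <- list()
  for (s in sets) {
    hit <- which(vapply(comps, function(m) length(intersect(m, s)) > 0,
                        logical(1)))
    if (length(hit)) {
      comps[[hit[1]]] <- union(Reduce(union, comps[hit]), s)
      if (length(hit) > 1) comps[hit[-1]] <- NULL
    } else comps[[length(comps) + 1L]] <- s
  }
  out <- data.frame(start = vapply(comps, min, numeric(1)),
                    end = vapply(comps, max, numeric(1)))
  out[order(out$start), , drop = FALSE]
}

# per-day enumeration oracle for person-time (one child)
oracle_person_time <- function(birth, followup_end, spells) {
  if (followup_end <= birth)
    return(data.frame(band = c("under1", "one_to_four", "five_to_ten"),
                      days_total = 0, days_in_hospital = 0))
  days <- seq(birth, followup_end - 1, by = "day")
  b1 <- add_years(birth, 1L); b5 <- add_years(birth, 5L)
  band <- ifelse(days < b1, "under1",
                 ifelse(days < b5, "one_to_four", "five_to_ten"))
  inhosp <- rep(FALSE, length(days))
  for (k in seq_len(nrow(spells)))
    inhosp <- inhosp | (days >= spells$start_date[k] &
                          days < spells$end_date[k])
  data.frame(
    band = c("under1", "one_to_four", "five_to_ten"),
    days_total = vapply(c("under1", "one_to_four", "five_to_ten"),
                        function(b) sum(band == b), numeric(1)),
    days_in_hospital = vapply(c("under1", "one_to_four", "five_to_ten"),
                              function(b) sum(inhosp & band == b), numeric(1)),
    row.names = NULL)
}

# write a code-list CSV and load it
make_codelist <- function(rows, ...) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(code = r[[1]], system = r[[2]], subgroup = r[[3]],
               category = r[[4]],
               match_mode = if (length(r) >= 5) r[[5]] else "prefix")))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  load_codelist(path, ...)
}

# minimal patients/deaths/admissions/school builders
make_patients <- function(ids, birth, sex = "female", gest = 39L, bw = 3300L,
                          mab = "25-29") {
  data.frame(patient_id = ids, birth_date = as.Date(birth), sex = sex,
             gestational_age_weeks = gest, birthweight_g = bw,
             maternal_age_band = mab)
}

no_deaths <- data.frame(patient_id = character(0),
                        death_date = as.Date(character(0)),
                        cause_codes = character(0))

make_admissions <- function(ids, start, end, method = "21", dx = "J069",
                            proc = "", birth_adm = FALSE, died = FALSE) {
  n <- max(length(ids), length(start))
  data.frame(admission_id = sprintf("T%04d", seq_len(n)),
             patient_id = rep_len(ids, n),
             admission_date = as.Date(rep_len(start, n)),
             discharge_date = as.Date(rep_len(end, n)),
             admission_method_code = rep_len(method, n),
             diagnosis_codes = rep_len(dx, n),
             procedure_codes = rep_len(proc, n),
             is_birth_admission = rep_len(birth_adm, n),
             died_in_hospital = rep_len(died, n))
}

make_school <- function(ids, year_group, academic_year, sen_level = "none",
                        primary_need = "none") {
  n <- max(length(ids), length(year_group))
  data.frame(patient_id = rep_len(ids, n),
             academic_year = rep_len(academic_year, n),
             year_group = rep_len(as.character(year_group), n),
             sen_level = rep_len(sen_level, n),
             primary_need = rep_len(primary_need, n))
}
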