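.datatable.aware <- TRUE

# non-standard-evaluation column names used in data.table expressions
utils::globalVariables(c(
  ".", ".BY", ".I", ".N", ".SD", ".drop", "N", "V1", "academic_year",
  "admission_date", "admission_id", "admission_ids", "admission_method_code",
  "age_band", "age_threshold", "aid", "ay", "band", "bday11", "bday5",
  "birth_date", "birthweight_g", "cause", "code", "code_system", "d",
  "days_at_risk", "days_in_hospital", "days_total", "death", "death_date",
  "died_in_hospital", "discharge_date", "dx", "e", "eleventh_birthday",
  "end_date", "enrolled_year1", "entry", "ever_ehcp", "ever_support",
  "expected_ay", "first_date", "first_method", "first_record_date",
  "flagged", "followup_end", "fup", "gestational_age_weeks", "group",
  "has_birth_admission", "has_record", "hi", "hi_y", "highest_ever", "i",
  "in_school_cohort", "is_birth_admission", "k", "len", "level", "lev",
  "lo", "lo_y", "match_mode", "maternal_age_band", "n_admissions", "n_any",
  "n_deaths", "n_ehcp", "n_enrolled", "n_events", "n_ever_ehcp",
  "n_ever_support", "n_group", "n_highest_ehcp", "n_highest_none",
  "n_highest_support", "n_pupils", "n_support", "new_spell", "nyr", "obs",
  "onset", "ord", "patient_id", "person_years", "pct", "prev_end",
  "primary_need", "primary_needs_ever", "proc", "rate_per_100py",
  "ref_rate", "s", "school_exclusion_reason", "sen_level", "sex", "side",
  "source", "spell_id", "spell_num", "spell_type", "src_ord", "start_date",
  "subgroup", "subgroups", "target", "variable", "via_death_only", "w",
  "x.aid", "year1_start", "year_group"))
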