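# neurophen

Phenotyping hospital-recorded neurodisability in children and describing
its prognostic footprint, from linked administrative health and education
records.

## The problem

Neurodisability is an umbrella term for long-term conditions involving
impairment of the brain or neuromuscular system with functional
limitations — autism, learning disability, epilepsy, cerebral palsy,
chromosomal and CNS anomalies, severe perinatal events, sensory
impairments, and related high-risk conditions. Individually many are
rare; together they mark out a small group of children with much higher
mortality, hospital admission rates and need for school support than
their peers. National hospital admission data (ICD-10 diagnoses, OPCS-4
procedures), linked mortality records and school-census records allow
this group to be identified and characterised at population scale — but
the underlying data are access-controlled and cannot be redistributed.

`neurophen` provides the full analysis as a tested, reusable R pipeline,
together with a seedable generator of linked synthetic records carrying
the same statistical structure, so every stage can be exercised,
calibrated and validated without the restricted data:

- **Code-list phenotyping** — normalised ICD-10/OPCS-4 code matching
  (prefix and exact semantics) over every diagnosis position of every
  admission before the 11th birthday, every procedure code, and every
  contributory cause of death, plus direct birth-characteristic triggers
  (gestational age < 27 weeks, birthweight < 1000 g). An illustrative
  code list covering the subgroup taxonomy ships with the package.
- **Cohort construction** — a birth cohort followed from birth to death
  or the 11th birthday, and a nested primary-school cohort with the
  exclusion cascade (died before Year 1; no linked school record; not
  enrolled in Year 1).
- **Hospital outcomes** — continuous inpatient spells (same-day transfer
  linkage, type from the earliest admission information), person-time at
  risk excluding in-hospital days, cumulative incidence of first
  recorded neurodisability by age (as a proportion of children and per
  100 person-years: rate = 100·cases / person-years, rate ratio vs the
  unaffected group), mortality by age at death, length of birth
  admission.
- **SEN outcomes** — ever-highest special-educational-needs provision
  (EHCP over SEN support over none) with Year-1 denominators, per-year
  proportions with year-specific denominators, and hospital↔school
  concordance by subgroup.
- **Reporting** — the cohort characteristics cross-tabulation with
  explicit missing-data rows, and small-cell disclosure control
  (primary suppression of counts below 10, complementary secondary
  suppression).

## Worked example

```r
library(neurophen)

cfg <- generator_config(n_children = 20000, seed = 2024)
syn <- generate_cohort_data(cfg)   # patients, admissions, deaths, school
run <- run_pipeline(run_config(data = syn))
print(run)
#> <neuro_run>
#>   inputs: 20000 patients, 47489 admissions, 93 deaths, 114472 school records
#>   birth cohort: 20000 children
#>   school cohort: 16578 children (died_before_year1=89, no_linked_school_record=3003, none=16578, not_enrolled_year1=330)
#>   phenotype: 744 flagged of 20000 (3.72%)
#>   spells: 46156 from 47489 admissions
#>   cumulative incidence: <1: 1.2%, <5: 2.5%, <11: 3.7%
```

3.72% of the simulated children carry a hospital-recorded
neurodisability subgroup by age 11. Admission rates per 100 person-years
at risk, with the unaffected children as reference:

```r
subset(run$rates, band == "under11" & group %in% c("none", "any"))
#>    group spell_type n_events person_years rate_per_100py rate_ratio
#> 4   none    planned     7250       211152          3.434         NA
#> 8    any    planned     2625         7720         34.003      9.903
#> 20  none  unplanned    13778       211152          6.525         NA
#> 24  any   unplanned     2506         7720         32.461      4.975
```

Affected children have about 10× the planned and 5× the unplanned
admission rate of their peers. Ever-SEN provision in the nested school
cohort (Year-1 enrolled denominators):

```r
subset(run$sen_summary, group %in% c("none", "any"),
       c(group, n_pupils, pct_any, pct_ever_support, pct_ever_ehcp))
#>   group n_pupils pct_any pct_ever_support pct_ever_ehcp
#> 1  none    16017    29.4             29.0           2.3
#> 2   any      561    72.2             53.5          38.3
```

Setting `output_dir` in `run_config()` writes every table
(`cohort.csv`, `phenotype.csv`, `spells.csv`, `person_time.csv`,
`rates.csv`, `mortality.csv`, `sen_summary.csv`, `concordance.csv`,
suppressed `characteristics.csv`, …) plus a `run.log` of stage row
counts.

Real data arrive the same way: point `run_config(input_dir = ...)` at a
directory with `patients.csv`, `admissions.csv`, `deaths.csv`,
`school.csv` (schemas in `?read_datasets`), and supply your own curated
code list via `load_codelist()`.

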