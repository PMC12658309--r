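Package: neurophen
Title: Phenotyping Childhood Neurodisability in Linked Hospital and Education Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies children with hospital-recorded neurodisability from
    ICD-10 diagnosis, OPCS-4 procedure and cause-of-death codes using a
    curated code list with prefix matching, and runs the full downstream
    descriptive analysis for a national birth cohort: continuous-inpatient
    spell linkage of admissions, person-time at risk excluding in-hospital
    days, cumulative incidence of first recorded neurodisability by age,
    planned and unplanned admission rates and rate ratios, mortality, length
    of birth admission, and special-educational-needs (SEN) provision in a
    nested primary-school cohort, including cross-record concordance between
    hospital subgroups and school-recorded needs. Includes a seedable
    generator of linked synthetic patient, admission, mortality and
    school-census records so every stage can be exercised and calibrated
    without access-controlled administrative data, and small-cell
    suppression for disclosure control of output tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
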