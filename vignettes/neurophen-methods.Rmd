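---
title: "Methods: phenotyping neurodisability and its outcomes in linked records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping neurodisability and its outcomes in linked records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurophen)
options(neurophen.quiet = TRUE)
```

This vignette documents the scientific content of `neurophen`: the
phenotyping algorithm and its conventions, the outcome definitions, the
generative model behind the synthetic data, the parameters that matter
and their defaults, numerical choices, and what the package's passing
tests do and do not establish about real data.

## The phenotype

A child has *hospital-recorded neurodisability* when any of the
following holds before their 11th birthday:

1. a code-list diagnosis appears in **any** position of an admission
   record (primary or secondary);
2. a code-list procedure (OPCS-4) appears in an admission;
3. a code-list code appears among the causes of death (underlying or
   contributory);
4. structured birth fields show gestational age **< 27 completed
   weeks** or birthweight **< 1000 g** (dated at birth; a missing field
   never triggers).

The code list maps normalised codes to named subgroups (autistic
spectrum disorders, epilepsy, cerebral palsy, …), each belonging to one
of eight categories (neurodevelopmental, complex neurologic,
inherited/congenital, high-risk brain, visual impairment, hearing
impairment, motor function, perinatal). Matching is by **prefix** by
default: hospital data record 4-character ICD-10 codes, so a
3-character list entry (e.g. `F84`) must capture all its children
(`F840`, `F841`, …). Exact-mode entries are available for codes whose
descendants must not match. Within one system and subgroup an entry
extending a shorter prefix entry is unreachable and is collapsed at
load time. The same matching path serves diagnoses, procedures and
causes of death.

The shipped list (`example_codelist()`) is an **illustrative
re-derivation** of the subgroup taxonomy from representative ICD-10
chapters and a few OPCS-4 procedures; it is not a clinically curated
published list, and analyses of real data should substitute one via
`load_codelist()`.

Per-child results carry the first record date overall and per subgroup,
the evidence source of the earliest record, and the age band of first
recording (`under5` vs `five_to_ten`), which drives the sensitivity
split used throughout the outputs.

**Open design points and how they were decided.**

* *Death-cause-only evidence.* Whether a phenotype seen only among
  causes of death should contribute a dated first record is ambiguous;
  we date it at death by default and expose
  `death_cause_dating = "exclude"`, under which such children stay
  flagged but have age band `none`.
* *Age at first record* uses the admission start date, since the
  admission is the analysis unit.
* Events on or after the 11th birthday are out of observation entirely.

## Cohorts and follow-up

The birth cohort covers births from 1 September 2003 to 31 August 2009,
followed from birth to death or the 11th birthday. Calendar (birthday
anniversary) arithmetic is used throughout; a 29 February anniversary
rolls forward to 1 March in non-leap years, so every child has exactly
one anniversary per year.

Year 1 — the first compulsory school year — begins on the 1 September
of the academic year in which the child turns 6: a child born between
1 September of year Y and 31 August of Y+1 starts Year 1 on 1 September
of Y+6. (A child born exactly on 1 September turns 6 on the first day
of that year; the package resolves this edge with an enumeration
oracle in its tests.) The nested school cohort applies exclusions in
order — death before the Year-1 start, then no linked school record,
then no Year-1 enrolment — and each excluded child carries the first
applicable reason, so reasons partition the excluded set. Because the
records do not define enrolment for year-repeaters, Year-1 enrolment
means a Year-1 record in the child's *expected* academic year by
default; `enrolment_rule = "any_year"` accepts any academic year.

Migration cannot be observed and is not modelled; follow-up is censored
only by death and the 11th birthday.

## Hospital outcomes

**Spells.** Admissions starting on the day of a previous discharge
(hospital transfers) or nested within an earlier admission's dates are
linked into one continuous inpatient spell; merging is transitive, and
the spell's planned/unplanned/birth type comes from the earliest
constituent admission's method code (elective `11/12/13`, emergency
`21–25/2A/2B`, birth `82` by default). Admissions that overlap an
earlier one without being nested or contiguous are dirty data; they are
merged with a warning rather than rejected.

**Person-time.** Follow-up days are split at the exact 1st, 5th and
11th birthday anniversaries into bands `<1`, `1–4`, `5–10`, and days
covered by spells are excluded from time at risk. Day counting is
date-difference (`discharge − admission`), so a same-day spell
contributes one spell but zero hospital days. Linked spells are
disjoint by construction, so no day is double-counted, and per-child
band totals sum exactly to the follow-up length.

**Cumulative incidence** is reported both ways the literature mixes:
the proportion of children with a first record before each threshold
birthday (1, 5, 11), and the rate per 100 person-years with person-time
accrued from birth to the first record, death, or the threshold —
whichever comes first. The threshold is strict (a record exactly on the
threshold birthday does not count).

**Admission rates** count spells (not raw admissions; a switch reverts
to admissions) per 100 person-years at risk, each spell attributed to
the age band of its start date — single attribution avoids double
counting when a spell straddles a birthday. Birth spells are excluded
from the planned/unplanned numerators (optionally reported as their own
stratum), and "other" admission methods never enter either count. Rate
ratios use the no-phenotype group as reference; a cell with zero
person-years yields a missing rate with a log entry.

**Birth admission length** summarises the spell containing the birth
admission (mean, SD, median, quartiles with the default type-7
convention); children with no birth admission are excluded with a
logged count.

## SEN outcomes

Provision levels are hierarchical: an Education, Health and Care Plan
(EHCP) over school-arranged SEN support over none. The *ever* measures
are cumulative over observed Reception–Year 6 records with the Year-1
enrolled cohort as denominator; ever-support and ever-EHCP overlap by
design (support commonly precedes a plan), while the highest-ever
classification partitions each group. Per-year proportions use
year-specific enrolment counts, which legitimately differ between
years. A pupil missing later years still contributes from the years
observed. Concordance relates hospital subgroups to school-recorded
primary needs through a fixed taxonomy map (e.g. hospital autistic
spectrum disorders ↔ school autistic spectrum disorder; chromosomal
anomalies ↔ learning disability, the school category that groups severe
and profound/multiple learning difficulties), with the subgroup's
school-cohort membership as denominator.

## Reporting conventions

Percentages are shown to 1 decimal place and rates to 2, rounded
**half-up** at the displayed precision (`round_half_up()`), the
convention least surprising in published tables; internal computation
keeps full precision, and stored rate tables always reproduce
`100·n/person-years` exactly. Missing data are retained as explicit
`Missing` rows in every characteristics block rather than imputed — the
analyses are descriptive and outcomes are complete, so imputation would
add assumptions without benefit.

Disclosure control masks counts strictly between 0 and 10 and, when
exactly one cell of a margin group is masked (so the margin would give
it away by subtraction), additionally masks the smallest remaining
cell. Percentages derived from masked counts are masked with them. This
simple per-block complementary rule is adequate at the complexity of
these tables; full cell-suppression optimisation is deliberately out of
scope.

## The synthetic-data generator

`generate_cohort_data()` emulates the *statistical structure* the
pipeline assumes, not the clinical reality of any dataset:

* **Subgroups** are Bernoulli draws per child with configurable
  prevalences (defaults echo a national cohort: developmental
  disorders, autism and epilepsy most common; implied any-subgroup
  prevalence `implied_any_prevalence()` ≈ 0.036–0.037). Subgroups are
  drawn independently, so comorbidity arises only as chance
  co-occurrence — the real joint distribution is unknown, and this is
  the documented default.
* **Evidence.** Every affected child carries at least one qualifying
  code: perinatal subgroups on the birth admission (with consistent
  birth fields — gestational age 23–26 weeks, birthweight < 1000 g),
  other subgroups attached to the admission nearest a target date drawn
  from a two-component age distribution (before 5 vs 5–10, weights
  2/3 : 1/3). Because perinatal dating forces those children under 5,
  the non-perinatal band draw is analytically reweighted so the
  *marginal* split matches the configured weights exactly. A small
  fraction of affected children who die carry their evidence only as a
  contributory cause of death. Within-band dating is uniform — a
  simplification, so by-age-1 incidence is *not* a calibrated quantity
  and real first-record age curves are not reproduced.
* **Admissions.** Counts are Poisson per child × age band × type with
  exposure equal to alive person-days and band-specific baseline rates
  (planned 3.66/3.67/3.21, unplanned 23.39/7.74/2.82 per 100
  person-years) multiplied by 10 (planned) and 4.8 (unplanned) for
  affected children. Lengths of stay are geometric; birth admissions
  keep the newborn at least overnight with configured means (1.5 vs 3
  days) chosen so the medians land at 1 vs 2 days. A child cannot be
  newly admitted while in hospital: stays truncate at the next
  admission, so index admissions map one-to-one onto spells and the
  injected same-day transfer continuations (probability 0.05) are what
  exercises the linkage. Exact birth dates are generated even though
  real admission data carry month of birth — a stated simplification.
* **Mortality.** Death risk 6.1% (affected) vs 0.3% by age 11, with
  age-at-death band weights derived from the corresponding published
  band counts; affected children's qualifying records are always dated
  no later than death.
* **School records.** 85% of children have any linked school record;
  given linkage and being alive at the year start, per-year enrolment
  probabilities are 0.94 (Reception) and 0.97–0.98 (Years 1–6),
  yielding a school cohort near 83% of births. SEN is parameterised as
  P(ever EHCP), P(ever support | EHCP), P(ever support | no EHCP) per
  status — chosen so the implied marginals
  (`implied_sen_marginals()`) are ever-EHCP 39.5% vs 2.4%, ever-support
  55.2% vs 29.8%, any provision 75.5% vs 30.3% — and unrolled into
  per-year levels with support preceding EHCP onset.
* **Needs and concordance.** Affected children with a mapped subgroup
  receive the corresponding school need with probability 0.7, otherwise
  (and for everyone else with provision) a baseline need distribution
  applies. Since a need is only observable given any provision, the
  *measurable* concordance is the composite
  `implied_concordance()` ≈ 0.53 for autism under the defaults, and
  recovery tests target that implied value.
* **Missingness** is missing-completely-at-random per field (sex 0.3%,
  gestational age 30.6%, birthweight 21.5%, maternal age 3.3%).
  Extremely preterm children additionally always carry a P07-family
  code at birth, so field missingness cannot hide them entirely.

Generation is deterministic given the seed and restores the caller's
RNG state.

**What passing tests show — and do not.** Parameter-recovery tests
demonstrate that the pipeline measures, without material bias, exactly
the quantities the generator encodes: prevalence, rate ratios on
person-time at risk, death proportions, SEN marginals, concordance.
They cannot validate the clinical code list, linkage error, coding-depth
drift over calendar time, comorbidity structure, or any feature of real
data the generator does not model; those require the restricted data
and external references.

## Problem sizes and numerical checks

The test suite verifies the fast implementations against brute-force
oracles: code matching against a naive scan over every entry (1,000
random codes), spell linkage against day-set connected components (500
random admission sets), and person-time against per-day enumeration
(100 random children). Parameter recovery runs on a 50,000-child cohort
with 3-standard-error Monte-Carlo bands; `scripts/acceptance.R` uses
150,000 children so that its noisiest reported percentage (mortality
among affected children) carries a relative Monte-Carlo error near 4%.
Invariant suites cover monotonicity of cumulative incidence in the age
threshold, person-time conservation, the SEN hierarchy partition,
suppression non-disclosure, and byte-identical end-to-end determinism.

## Known limitations

* The shipped code list is illustrative; subgroup-level results on real
  data depend entirely on the curated list supplied.
* Independence of subgroups understates real comorbidity; subgroup
  counts sum to more than the any-phenotype count by design, but the
  generator's overlap is thinner than reality's.
* Outpatient and emergency-department contacts, multiple births,
  linkage error and migration are out of scope.
* Uniform within-band first-record dating means fine-grained
  age-at-first-diagnosis curves should not be read off synthetic runs.
* The secondary-suppression rule protects single blocks with published
  margins; it does not attempt cross-table consistency.
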