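---
title: "Validating knee-OA phenotyping algorithms: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating knee-OA phenotyping algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaphen)
```

## The validation design

A case-identification (phenotyping) algorithm labels a patient as having
knee osteoarthritis from coded events alone. To measure how well such
labels track real disease, each algorithm's decisions are cross-tabulated
against a reference standard built from data the algorithm never sees:
GP-questionnaire confirmation of knee pain lasting more than six weeks,
plus an x-ray or MRI report demonstrating OA. Keeping the index test
(codes) and the reference standard (questionnaire + imaging report)
disjoint is what makes the PPV and sensitivity estimates meaningful; the
package enforces this split structurally — `adjudicate_cohort()` reads
only questionnaires and imaging-report findings, `evaluate_all()` reads
only coded events (and imaging dates, for the imaging-restricted
variants).

The pipeline is: cohort input → index-date assignment and eligibility →
exclusions → gold-standard adjudication → rule evaluation → two-by-two
statistics.

## The rule engine and its assumptions

An `algorithm_definition()` has a count rule per code category
(`exactly_one` or `at_least(k)`), an optional window, a minimum
separation, and an optional imaging-proximity bound. Fixed
interpretations, all configurable:

* **Calendar arithmetic is in whole days.** "Six months" = 183 days,
  "12 months" = 365, "2 years" = 730. Month arithmetic is ambiguous
  (which month?); fixed day counts make every decision reproducible.
* **Separation bounds are inclusive.** "Separated by at least 7 days"
  means a date difference of exactly 7 qualifies. Likewise a pair exactly
  183 days apart satisfies a 6-month window.
* **"One code" means exactly one code of that category in the whole
  record**, with no constraint on the other category. This follows the
  source tables' footnote; under an "at least one" reading the one-code
  rows would be supersets of the two-code rows, which the published
  counts contradict.
* **The 7-day separation also applies to the mixed OA + pain rule.** The
  cohort-selection wording applies the separation to "2 or more codes for
  OA and/or knee pain"; a same-day OA + pain pair (one GP visit) is
  therefore not a qualifying pair by default. Set
  `default_algorithms(mixed_rule_separation_days = 0)` for the permissive
  reading.
* **Imaging proximity is symmetric**: an imaging code or coded report
  within ±730 days of any qualifying diagnosis code. The source text says
  "within 2 years of diagnosis" without a direction; symmetric is the
  least-assuming reading, and the per-row fixtures place imaging at the
  index date, where the direction does not matter.
* **Rheumatic-disorder exclusions scan the whole record** (two codes ≥7
  days apart for RA, gout, pseudogout, or psoriatic arthritis); only the
  total-knee-replacement exclusion is anchored *before* the index date.
  The sentence structure of the source supports this split, though it is
  genuinely ambiguous. One primary reason is logged per excluded patient
  under the fixed priority RA > gout > pseudogout > psoriatic arthritis >
  TKR > insufficient data, so the exclusion log is deterministic when a
  patient has several conditions.
* **Registration look-back**: eligibility requires ≥365 registered days
  before the index date with a spell overlapping the assessment period
  (2000-01-01 to 2015-05-31). Age is index year minus birth year, since
  anonymised primary-care extracts carry birth year only.

The engine is checked against brute-force oracles that re-derive the
semantics by exhaustive enumeration over pairs/subsets — the tests never
let the engine validate itself.

## Validation statistics

PPV = 100·TP/(TP+FP) and sensitivity = 100·TP/(TP+FN). Confidence
intervals use the **Wald normal approximation** with `z = qnorm(0.975)`,
clipped to [0, 100]. The original analysis names only a software option,
not an interval family; Wald was adopted because it reproduces every
printed interval from its integer counts — for example 25/39 →
(49.0, 79.2) and 11/12 → (76.0, 100.0) — whereas exact Clopper–Pearson
intervals do not. The package verifies this across all 32 printed
intervals before anything else is trusted (`test-acceptance.R`).

Two whole-table constants are derived, not printed: the gold-positive
denominators 57 (of 85) and 43 (of 62). Each is the unique integer
consistent with *every* printed sensitivity in its table (e.g.
round(100·25/d, 1) = 43.9 forces d = 57) and with the printed 67%
prevalence; the test suite re-checks this consistency for every row.

Rounding is half away from zero to one decimal (`round_half_up()`); base
R's round-half-to-even would disagree at ties. Ties at x.x5 never occur in
the published values, so the tie behaviour itself is untestable against
the source. Undefined quantities (empty denominators) are reported as
`NA`, never 0 or 100, and degenerate intervals at k = 0 or k = n collapse
to the point estimate.

## The synthetic generator: what it emulates

`generate_cohort()` targets the *marginal* structure of the analysed
validation sample: latent gold-standard prevalence 0.67; age at index from
a truncated normal (mean 63.8, SD 11.1, support 40–90, drawn by inverse
CDF from the single seeded uniform stream); 53% women; 60% of patients
with ≥1 OA code; 78% with ≥1 pain code; 73% with coded imaging.

Two derived parameter choices deserve explanation:

* **Conditional code probabilities.** Only marginals are stated, and
  cohort selection guarantees every patient ≥1 OA-or-pain code. The
  generator draws "carries OA codes" at 0.70 (cases) / 0.40 (controls),
  giving a 0.601 marginal at prevalence 0.67; patients without OA codes
  always carry pain codes, and patients with OA codes carry pain codes at
  0.70 / 0.40 (cases/controls), giving a 0.780 pain marginal. These
  conditionals are the package's own choice (cases should carry more OA
  codes than controls); any pair reproducing the marginals would do.
* **Repeat-code gaps** are uniform on 7–320 days: repeat consultations
  for a chronic joint problem are typically weeks to months apart. This makes
  the 6- vs 12-month windows genuinely discriminating in generated data
  (with all gaps under 183 days the two window variants would be
  indistinguishable, and the window-monotonicity property would hold only
  vacuously).

Imaging reports are emitted with findings flags *and* a canned text
string, and the thin keyword mapper (`report_flags_from_text()`) is tested
to recover the flags exactly — it handles the generator's canned strings
only, not free-text radiology (no negation handling; real report NLP is
out of scope). Questionnaire answers agree with latent status at 0.95
(cases) / 0.60 (controls) — controls were selected for knee-pain codes,
so many truly have pain without radiographic OA; imaging reports
demonstrate OA at 0.92 (cases) / 0.15 (controls). Patients without coded
imaging receive GP-transcribed findings with probability 0.8, mirroring
the observation that most subjects without imaging codes still had
findings in GP notes.

What a green generator test establishes: the marginals above are
recovered within binomial/normal sampling error at n = 2000, cohorts are
valid and eligible, and the same seed reproduces the same cohort byte for
byte. What it does **not** establish: realistic practice-level coding
variation, code hierarchies, visit clustering, secular trends, or any
joint dependence beyond the case/control conditioning — the generator is
a stated marginal world, not a model of a real database. Note the
*adjudicated* positive share in generated data (≈56–58%) is below the
latent 67%, because adjudication requires an available report and a
confirmed pain answer; the published 67% describes patients who all had
sufficient gold-standard data.

## Fixtures: per-row, not one joint cohort

Each published table row gets its own deterministic 85- (or 62-) patient
fixture in which exactly `n_satisfying` patients meet the named
definition, `n_tp` of them gold-positive. A single cohort jointly
reproducing *all* rows cannot exist under the plain reading: 60% of 85
with ≥1 OA code is 51 patients, but the "exactly one OA code" row (39)
plus the "≥2 OA codes within 12 months" row (14) already needs 53.
Whether the 60% is misrounded or the one-code rows mean something subtler
cannot be resolved from the source, so the package reproduces rows
independently and documents the tension here. Qualifying code pairs sit
at day offsets 0/30 (inside six months) or 0/300 (inside twelve, outside
six); every fixture patient carries a coded imaging report at index, so
the same construction serves the imaging-restricted variants, where the
62-patient fixture *is* the imaging subcohort.

The 93-subject attrition fixture injects 4 gout, 2 RA, 1 TKR-before-index
and 1 insufficient-data patient; the exclusion stage must retain exactly
85 with that reason histogram.

## Degenerate inputs and tie-breaks

Empty cohorts: `evaluate_all()` returns a 0-row matrix;
`summarize_cohort()` errors (a mean age of nothing is not 0). A same-day
OA/pain tie at the index is immaterial — the index is a date, not a code.
Duplicate same-day codes never satisfy a separation rule. Patients whose
gold standard is indeterminate are excluded before contingency tables are
built; `contingency()` refuses them rather than silently dropping rows.

## Known limitations

* Code sets other than the five published knee-pain Read codes are
  synthetic placeholders (the authoritative appendix lists were never
  published); real analyses must supply their own `codesets.yaml`.
* The rule language covers count/window/separation/proximity rules only —
  exactly what the eight algorithms need, not a general temporal logic.
* No NPV/specificity (not reported in the source design), no ROC, no
  hierarchy-aware code matching, no free-text NLP.
* The three-stratum sampling design of the original 100 subjects (25 OA
  with imaging / 25 OA without / 50 pain with imaging) is not modelled;
  it is not recoverable from the published counts.
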