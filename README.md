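# oaphen

Validation of knee-osteoarthritis case-identification algorithms in coded
primary-care records.

## The problem

Large EHR and claims databases identify knee osteoarthritis (OA) cases with
*phenotyping algorithms*: computable rules over coded diagnostic events,
such as "at least two knee-OA Read codes within six months, separated by at
least seven days". Before such an algorithm is trusted in an epidemiologic
or genetic study, its diagnostic performance has to be measured against a
reference ("gold") standard — here, symptomatic imaging-confirmed disease:
knee pain lasting more than six weeks together with an x-ray or MRI report
demonstrating OA (definite osteophytes, joint space narrowing, or a
radiologist's impression of OA; sclerosis or tibial spiking alone do not
qualify).

For an algorithm with decisions cross-tabulated against the gold standard
(TP/FP/FN/TN), the package reports

* **PPV** = 100 · TP / (TP + FP) — of algorithm positives, the percent
  truly diseased;
* **Sensitivity** = 100 · TP / (TP + FN) — of the diseased, the percent the
  algorithm finds;

each with a Wald 95% confidence interval `p ± z·√(p(1−p)/n)`
(z = 1.959964), clipped to [0, 100], everything rounded half away from zero
to one decimal.

This package is for methodologists building or auditing such validation
studies: it provides the cohort I/O, the eligibility and exclusion
filtering, a declarative temporal rule engine for the algorithms, rule-based
gold-standard adjudication, the validation statistics, a synthetic
longitudinal cohort generator, and a one-command reproduction of the
published validation tables it was built around.

## Worked example

Reproduce the first published validation row ("one OA code", 85 analysed
subjects of whom 57 are gold-standard positive, 39 satisfying the
definition, 25 of them true positives) through the *full* pipeline — the
fixture only lays out coded events, imaging findings and questionnaire
answers; every statistic below is computed by the engine:

```r
library(oaphen)

fx   <- build_row_fixture("one_oa_code", 85, 57, 39, 25)
gold <- adjudicate_cohort(fx$cohort)
dec  <- evaluate_all(fx$cohort, list(fx$algorithm))
val  <- validate_algorithms(dec, gold,
                            labels = c(one_oa_code = fx$algorithm$label))
format_validation_table(val)
#>   Definition N satisfying N true positive      PPV (95% CI) Sensitivity (95% CI)
#>  One OA code           39              25 64.1 (49.0, 79.2)    43.9 (31.0, 56.7)
```

So 64.1% of patients flagged by a single OA code truly have
imaging-confirmed symptomatic knee OA, but the rule finds only 43.9% of the
true cases — the PPV/sensitivity trade-off that motivates multi-code rules.

The attrition stage on the shipped 93-subject fixture:

```r
excl <- apply_exclusions(build_exclusion_fixture())
table(excl$outcomes$reason[excl$outcomes$excluded])
#>              gout insufficient_data                ra  tkr_before_index
#>                 4                 1                 2                 1
nrow(excl$cohort$patients)
#> [1] 85
```

A synthetic cohort with the validation sample's marginal structure:

```r
co <- generate_cohort(generator_params(2000, seed = 3))
summarize_cohort(co, adjudicate_cohort(co))
#>      n mean_age sd_age pct_women pct_oa_code pct_pain_code pct_imaging pct_gold_positive
#> 1 2000     63.7   10.4        52          61            78          74                58
```

(`pct_gold_positive` is the share *adjudicable as positive* from the
generated questionnaires and reports; the latent disease prevalence, 67% by
default, is returned in `attr(co, "latent")`.)

Reproduce every published table cell and exit non-zero on any mismatch:

```sh
Rscript inst/cli/oaphen.R reproduce-paper
```

or in R: `reproduce_paper(verbose = TRUE)`.

## Layout

* `R/` — cohort model and I/O, code sets, eligibility/exclusions, rule
  engine, gold standard, validation statistics, synthetic data, pipeline.
* `inst/extdata/` — default `codesets.yaml` (only the knee-pain Read codes
  are authoritative; other sets are marked synthetic placeholders) and
  `algorithms.yaml` (the eight published algorithms plus imaging-restricted
  variants).
* `inst/cli/oaphen.R` — command-line interface (`generate`, `classify`,
  `adjudicate`, `validate`, `report`, `run`, `fixtures`,
  `reproduce-paper`).
* `vignettes/validating-knee-oa-phenotypes.Rmd` — the methods vignette:
  model, assumptions, parameter choices, and limitations.
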