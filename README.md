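# cardext

Fuzzy symptom and medication extraction from hospital discharge summaries,
with gender-disparity statistics — and a synthetic-corpus generator so the
whole pipeline is testable without patient data.

## The problem

In many hospitals — especially in low- and middle-income settings — the
richest clinical information sits in free-text discharge summaries. For
acute myocardial infarction (AMI), two questions matter for equity of care:
do women and men *present* with different symptoms (chest pain vs shortness
of breath, nausea, or culturally specific terms such as the Urdu *ghabrahat*,
"a sense of impending doom"), and are they *prescribed* guideline therapy
(aspirin, statins, clopidogrel, β-blockers) at the same rates? Answering
either requires turning thousands of heterogeneous narratives into
patient-level indicators. `cardext` implements that pipeline for R users:

1. **Passage location** — find the presenting-complaint passage by section
   headings, falling back to trigger phrases ("presented with", ...).
2. **Fuzzy symptom matching** — slide k-token windows over the passage and
   score them against a symptom lexicon with normalized Levenshtein
   similarity, `sim(a,b) = 100·(1 − LEV(a,b)/max(|a|,|b|))`, keeping hits
   with `sim ≥ 80` (inclusive; "chest pian" vs "chest pain" scores exactly
   80 and counts).
3. **Negation handling** — a hit is suppressed when a cue (*no, not, denies,
   denied, without, nil*) occurs within 3 tokens before it in the same
   sentence.
4. **Medication extraction** — detect discharge-medication tables, reduce
   rows to base terms by rule ("Tab Ascard 75mg OD" → "ascard"), classify
   into 9 drug classes via a dictionary with a strict fuzzy fallback
   (threshold 90); unmatched terms go to a manual-review queue.
5. **Disparity statistics** — per-outcome 2×2 tables (exposure = woman),
   odds ratios `OR = ad/bc` with Woolf CIs
   `exp(ln OR ± z·√(1/a+1/b+1/c+1/d))` (zero-cell tables are *omitted*, not
   continuity-corrected), uncorrected Pearson chi-square, Mann-Whitney, and
   covariate-adjusted ORs from logistic regression (Wald CIs).
6. **Synthetic corpora** — `generate_corpus()` renders documents from
   configurable per-gender prevalences with typo and negation injection and
   emits matched ground truth, enabling precision/recall evaluation and
   parameter-recovery checks.

See `vignettes/cardext-methods.Rmd` for the model, the defaults and the
design rationale.

## Worked example

```r
library(cardext)

gen    <- generate_corpus(synth_config(2000, seed = 7))
sym    <- extract_corpus_symptoms(gen$docs)
med    <- extract_corpus_medications(gen$docs)
cohort <- build_cohort(gen$docs, sym, med)

cohort$flow
#> $total            [1] 2000
#> $with_symptoms    [1] 1074
#> $without_symptoms [1]  926
#> $with_meds        [1] 1603
#> $without_meds     [1]  397

odds_ratio_univariate(contingency(cohort, "chest pain"))
#> OR 0.653 (95% CI 0.509-0.839), p = 0.000842 [univariate_woolf]

odds_ratio_adjusted(cohort, "chest pain")   # adjusts for diabetes, age group
#> OR 0.660 (95% CI 0.514-0.848), p = 0.00118 [logistic_adjusted]

head(render_tables(cohort)$symptoms, 3)
#>              outcome total_n total_pct women_n women_pct men_n men_pct      p_value
#>           chest pain     793     65.43     228     58.76   565   68.57 8.127793e-04
#>  shortness of breath     486     40.10     191     49.23   295   35.80 8.617571e-06
#>  sweating or diaphoresis   82      6.77      17      4.38    65    7.89 2.334012e-02
```

Reading: of 2000 synthetic summaries, 1074 had at least one detected
presenting symptom and 1603 a detected medication table. Among passage-bearing
records, women had 0.65 times the odds of men of presenting with chest pain
(95% CI 0.51–0.84) — the generator's configured disparity, recovered by the
full extract-then-analyze pipeline. The adjusted estimate barely moves
because the simulated covariates are independent of gender.

A command-line interface wraps the same stages (`simulate`,
`extract-symptoms`, `extract-meds`, `stats`, `evaluate`, `run`); see
`?cardext_main` and the launcher in `inst/exec/cardext`.

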