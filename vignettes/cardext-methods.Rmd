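---
title: "Extraction model and disparity statistics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extraction model and disparity statistics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package does

`cardext` turns free-text hospital discharge summaries of patients admitted
with acute myocardial infarction (AMI) into patient-level binary indicators —
which presenting symptoms were documented, which drug classes were prescribed
at discharge — and computes gender-disparity statistics on those indicators.
Because real discharge summaries cannot be shared, the package also ships a
synthetic-corpus generator with known ground truth, so every stage of the
pipeline is testable end to end.

```{r, eval = FALSE}
library(cardext)
gen <- generate_corpus(synth_config(500, seed = 1))
sym <- extract_corpus_symptoms(gen$docs)
med <- extract_corpus_medications(gen$docs)
cohort <- build_cohort(gen$docs, sym, med)
render_tables(cohort)
```

## The symptom extraction model

**Passage location.** Presenting complaints are documented near the start of
a summary, but heading conventions vary. `extract_presenting_passage` first
looks for a section heading matching a presenting-complaint pattern
("presenting complaints", "chief complaint", "history of present illness",
...); failing that it falls back to the earliest passage containing a trigger
phrase ("presented with", "complaints of", ...). Documents with neither
produce an *absent* passage — a valid outcome that feeds the pipeline's flow
accounting (documents with no detected symptoms), not an error. Only the
presenting passage is searched: remarks later in a summary about resolving
symptoms are deliberately out of scope.

**Fuzzy matching.** Clinical text contains typos and spelling variants, so
concept detection uses normalized Levenshtein similarity on a 0–100 scale:

$$\mathrm{sim}(a, b) = 100 \left(1 - \frac{\mathrm{LEV}(a,b)}{\max(|a|, |b|)}\right)$$

with unit-cost character edits. For each lexicon synonym of $k$ tokens, a
$k$-token window slides over the passage tokens; a window scoring at or above
the threshold (default **80**) emits a match. The threshold is *inclusive*:
the canonical boundary case, a transposed "chest pian" against "chest pain",
scores exactly 80 ($\mathrm{LEV} = 2$, length 10) and counts as a match.
Treating the threshold as exclusive would silently drop exactly the class of
single-transposition typos the fuzzy matcher exists to absorb. Overlapping
windows hitting the same concept are merged into the single highest-scoring
match (ties: earliest window); two different concepts may share a span, since
concepts are independent binary outcomes downstream. The similarity function
is fixed to this one formula — not token-set or partial-ratio variants — so
every decision the matcher takes is reproducible from the definition.

**Negation.** A match is negated when a cue token (default set: *no, not,
denies, denied, without, nil*) occurs among the `window_tokens` (default
**3**) tokens immediately preceding the match, without crossing a sentence
boundary (".", ";", newline). The preceding-side window is the minimal
reading of cues like "no chest pain"; the window size, cue set and
sentence-bounding are all configurable. A concept whose only matches are
negated never enters `symptoms_present`.

**Lexicon.** The builtin lexicon has 18 canonical symptom concepts —
including the Urdu loanword *ghabrahat* ("a sense of impending doom", a
culturally specific AMI presentation in Pakistani patients) — each with
common-sense synonyms ("sob" for shortness of breath, the "ghabrat" spelling
variant, and so on). Expert-refined synonym lists from clinical practice are
not publicly available, so the shipped lexicon is a reconstruction and is
fully user-replaceable via a JSON file. A lexicon-level test guards that no
two synonyms of *different* concepts reach similarity 80, which would make
even a typo-free corpus ambiguous.

## The medication extraction model

Discharge medications appear as tabular sections near the end of a summary.
`detect_medication_tables` finds indicator headings ("discharge
medications", ...) and collects the non-empty row strings up to the next
heading. Each row is reduced to a *base term* by rule: strip leading dosage
forms (tab, cap, inj, syp, susp), strip trailing dose/route/frequency tokens
(75mg, 10 units, OD, BD, SC, ...), keep the first 1–3 remaining tokens.
Classification is an exact dictionary lookup into nine drug classes (aspirin,
statin, clopidogrel, beta-blocker, antidiabetic, ACE-inhibitor, ARB,
aspirin–clopidogrel combination, ticagrelor), with a fuzzy fallback at
threshold **90** — stricter than symptom matching because sound-alike drug
names are a real safety hazard; ties break lexicographically so
classification is a total, deterministic function. Unmatched terms are
reported as UNKNOWN and aggregated into a frequency report that stands in
for the manual-labeling step a production deployment would have. Combination
pills are their own class, distinct from their components listed separately;
a document listing both a combination pill and separate aspirin reports both.

## Statistics

With exposure *woman* and outcome a symptom or drug class, each 2×2 table
yields the odds ratio $\mathrm{OR} = ad/bc$ with the Woolf (log-normal)
interval $\exp(\ln \mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/a + 1/b + 1/c +
1/d})$. Woolf intervals were chosen because recomputing the reference
intervals from published per-gender counts reproduces them at printed
precision, identifying the method. Tables with any zero cell are *omitted*
(no continuity correction): an explicit "not estimable" is more honest than
a correction-dependent number, and matches the reporting convention of the
reference analysis. Group comparisons use the uncorrected Pearson chi-square
(1 df; undefined with a zero margin, reported as NA with a warning) and a
two-sided Mann-Whitney test (exact null distribution when both groups have
≤ 20 tie-free observations, tie-corrected normal approximation otherwise).

Adjusted odds ratios come from maximum-likelihood logistic regression of the
outcome on gender plus covariates (IRLS, tolerance $10^{-12}$, ≤ 100
iterations), reporting the exponentiated gender coefficient with its Wald
95% CI. Symptom models adjust for diabetes and the binary age grouping
(< 45 vs ≥ 45 years, the age cut at which AMI presentation is known to
differ); medication models adjust for diabetes, percutaneous intervention
and admission year (centered, continuous — the parsimonious encoding;
a categorical encoding is possible by passing a factor column). Binary age
grouping is the default for symptom models because the analysis design is
stated in terms of that comparison; continuous `age_years` is accepted as a
covariate name too. Constant covariates are dropped, so with all covariates
constant the adjusted estimate reduces to the univariate OR (tested to six
decimals). Non-convergence and separation (|coefficient| > 15 or a Wald SE
> 100) yield an omitted result with a reason rather than a number. P-values
for both univariate and adjusted ORs are Wald tests.

**Denominators.** Frequency tables and ORs for symptoms are computed over
records where a presenting-complaint passage was located; medication
outcomes over records with a detected medication table. This "extraction
found content" restriction — rather than "at least one symptom detected" —
keeps the configured per-gender prevalences equal to the observed
conditional prevalences in synthetic cohorts. Conditioning on a non-empty
extracted set would inflate every per-gender prevalence by a different
factor and shift odds ratios away from their configured values, making
parameter-recovery checks incoherent.

## The synthetic world

`synth_config` defaults state one fixed reference scenario, chosen once:

* **Cohort composition**: 33% women (1769/5358); a presenting-complaint
  passage in 60.0% of women's and 63.5% of men's summaries (1061/1769,
  2278/3589); a medication table in 80.3% of summaries (4301/5358).
* **Symptom prevalences** (conditional on a passage): the per-gender rates of
  the 18 concepts in the reference cohort, e.g. chest pain 56.3% of women vs
  68.8% of men, shortness of breath 49.5% vs 37.7%, ghabrahat 5.1% vs 3.7%.
* **Medication prevalences** (conditional on a table): per-gender
  probabilities are not published directly; they are recovered numerically
  (by `uniroot`) from the overall class prevalence, the univariate
  women-vs-men OR and an assumed women fraction of 1769/5358, e.g. statin
  92.1% overall with OR 0.62.
* **Covariates**: age normal with means 67.8 (women) / 63.3 (men); the SD
  (12 y) is not published and was chosen as realistic for an AMI cohort.
  Diabetes prevalence 0.55 (back-derived from published subgroup counts:
  ~1826 of 3339 symptomatic patients); PCI 0.60 (typical for AMI admissions,
  not published); admission year uniform on 2010–2018.
* **Noise**: `typo_rate` 0.05 (one random character edit per affected
  mention word) and `negation_rate` 0.05 — modest rates plausible for typed
  clinical text; both are dials for stress-testing, with 0 defining the
  "clean" corpora used in exactness tests.
* **Templates**: three English frames (heading-led section, trigger-phrase
  narrative, one-symptom-per-line table) weighted 0.5/0.3/0.2, reflecting
  heterogeneous real-world formatting. Mentions use the canonical name or,
  with probability 0.2, a random synonym.

**Negation semantics.** Ground-truth symptoms are drawn first, at the
configured prevalences, and are never retracted. Explicit denials are then
added for *absent* concepts (probability `negation_rate` × prevalence),
rendered with cues from the extractor's own cue set so generator and
extractor agree on the negation vocabulary by construction. The alternative
— negating a fraction of true mentions — would multiply every true
prevalence by (1 − `negation_rate`) and silently break the generator's
prevalence contract.

**What a green test does not establish.** The generator produces short,
well-formed English documents with single-character typos. It does not model
OCR noise, dictation artifacts, Urdu-script text, hedging ("cannot rule out
chest pain"), family history mentions, or free-text medication narratives.
Exactness results on clean synthetic corpora certify the mechanics of the
pipeline, not clinical-grade accuracy on real summaries; on real data the
lexicon and patterns must be reviewed by local experts.

## Numerical and degenerate-input conventions

* Two empty strings have similarity 100; similarity is symmetric and equals
  100 iff the normalized strings are equal.
* Character offsets are 0-based and half-open; token indices likewise.
* Empty corpora, documents without passages or tables, and all-false
  outcomes produce empty results or omitted estimates, never errors.
* All randomness flows through R's global RNG from a single integer seed,
  advanced in document order; identical configuration and seed reproduce a
  corpus byte for byte.

## Known limitations

* The fuzzy-match threshold (80) is treated as a given constant; the
  preliminary tuning that produced it is not reproducible here.
* Negation handling is proximity-based only — no scope parsing, no hedge or
  uncertainty detection.
* The medication model covers the nine analysis classes; everything else is
  UNKNOWN by design, and dose/frequency information is discarded.
* Adjusted-OR p-values are Wald; likelihood-ratio tests are not implemented.
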