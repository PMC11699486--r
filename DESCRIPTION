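Package: cardext
Title: Fuzzy Symptom and Medication Extraction from Discharge Summaries
    with Gender-Disparity Statistics
Version: 0.1.0
Authors@R:
    person("cardext", "developers", email = "cardext@example.org",
           role = c("aut", "cre"))
Description: Extracts presenting symptoms of acute myocardial infarction and
    discharge medication classes from free-text hospital discharge summaries.
    Symptom detection uses fuzzy phrase matching (normalized Levenshtein
    similarity on a 0-100 scale, threshold 80) over a configurable symptom
    lexicon, with proximity-based negation handling. Medication rows are
    normalized to base terms by rule and classified into nine drug classes via
    a dictionary with a fuzzy fallback. On top of the extracted indicators the
    package computes gender-disparity statistics: 2x2 contingency tables,
    Pearson chi-square and Mann-Whitney tests, univariate odds ratios with
    Woolf confidence intervals, and covariate-adjusted odds ratios from
    logistic regression. A synthetic discharge-summary generator with known
    ground truth (configurable prevalences, typo and negation injection) makes
    the whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
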