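# Medication-table row parsing, base-term normalization and drug-class
# classification (exact dictionary lookup with a strict fuzzy fallback).

FORM_TOKENS <- c("tab", "tabs", "cap", "caps", "inj", "syp", "susp")
ROUTE_FREQ_TOKENS <- c("od", "bd", "tds", "qid", "prn", "sc", "po", "iv")
UNIT_TOKENS <- c("mg", "g", "ml", "mcg", "unit", "units")
DOSE_TOKEN_RX <- "^[0-9]+(\\.[0-9]+)?(mg|g|ml|mcg|units?)?$"

#' Extract the base term from a medication row
#'
#' Normalizes the row, strips leading dosage-form tokens (tab, cap, inj, syp,
#' susp), strips trailing dose/route/frequency tokens (numbers with optional
#' mg/g/ml/mcg/units suffix; od, bd, tds, qid, prn, sc, po, iv) and returns
#' the first remaining run of 1-3 tokens ("" if nothing remains).
#'
#' @param row Medication row string, e.g. \code{"Tab Ascard 75mg OD"}.
#' @return Lowercase base term, e.g. \code{"ascard"}.
#' @export
extract_base_term <- function(row) {
  toks <- strsplit(normalize_term(row), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  while (length(toks) && toks[1] %in% FORM_TOKENS) toks <- toks[-1]
  while (length(toks) && (grepl(DOSE_TOKEN_RX, toks[length(toks)]) ||
                          toks[length(toks)] %in% ROUTE_FREQ_TOKENS ||
                          toks[length(toks)] %in% UNIT_TOKENS))
    toks <- toks[-length(toks)]
  if (!length(toks)) return("")
  paste(toks[seq_len(min(3L, length(toks)))], collapse = " ")
}

#' Classify a medication base term into a drug class
#'
#' Exact dictionary lookup first; on a miss, a fuzzy lookup over dictionary
#' names using \code{\link{similarity}} at \code{fuzzy_threshold} (default 90,
#' stricter than symptom matching because sound-alike drug names are risky);
#' highest-scoring name wins, ties broken by lexicographic order of the
#' dictionary name. Terms that still miss return \code{"UNKNOWN"}.
#'
#' @param base_term Normalized base term.
#' @param dictionary A \code{cardext_meddict}.
#' @param fuzzy_threshold Similarity threshold for the fuzzy fallback.
#' @return A drug-class label or \code{"UNKNOWN"}.
#' @export
classify_medication <- function(base_term, dictionary = load_medication_dictionary(),
                                fuzzy_threshold = 90) {
  if (is.na(base_term) || !nzchar(base_term) || nrow(dictionary) == 0L)
    return("UNKNOWN")
  i <- match(base_term, dictionary$name)
  if (!is.na(i)) return(dictionary$class[i])
  sims <- similarity_matrix(base_term, dictionary$name)[1, ]
  best <- max(sims)
  if (best < fuzzy_threshold) return("UNKNOWN")
  cand <- dictionary$name[sims == best]
  dictionary$class[match(sort(cand)[1], dictionary$name)]
}

#' Extract discharge-medication classes for one summary
#'
#' Composes \code{\link{detect_medication_tables}},
#' \code{\link{extract_base_term}} and \code{\link{classify_medication}}.
#' Combination products (e.g. an aspirin-clopidogrel pill) map to their own
#' class, distinct from separate aspirin and clopidogrel rows.
#'
#' @param doc A \code{cardext_summary}.
#' @param dictionary A \code{cardext_meddict}.
#' @param fuzzy_threshold Fuzzy-lookup threshold (default 90).
#' @param indicators Medication-table indicator phrases.
#' @param patterns Heading regexes delimiting table regions.
#' @param .class_cache Optional environment memoizing term classifications
#'   across a corpus (used by \code{\link{extract_corpus_medications}}).
#' @return A \code{cardext_meds}: list with \code{doc_id}, \code{rows_seen},
#'   \code{classified} (character vector of detected classes),
#'   \code{unknown_terms} (deduplicated unmatched base terms) and
#'   \code{meds_found} (at least one table region with >= 1 classified row).
#' @export
extract_patient_medications <- function(doc,
                                        dictionary = load_medication_dictionary(),
                                        fuzzy_threshold = 90,
                                        indicators = medication_indicator_terms(),
                                        patterns = heading_patterns(),
                                        .class_cache = NULL) {
  regions <- detect_medication_tables(doc$text, indicators, patterns)
  rows <- unlist(lapply(regions, `[[`, "rows"), use.names = FALSE)
  if (is.null(rows)) rows <- character(0)
  terms <- vapply(rows, extract_base_term, "", USE.NAMES = FALSE)
  classify1 <- function(term) {
    if (is.null(.class_cache) || !nzchar(term))
      return(classify_medication(term, dictionary, fuzzy_threshold))
    if (exists(term, envir = .class_cache, inherits = FALSE))
      return(get(term, envir = .class_cache, inherits = FALSE))
    hit <- classify_medication(term, dictionary, fuzzy_threshold)
    assign(term, hit, envir = .class_cache)
    hit
  }
  classes <- vapply(terms, classify1, "", USE.NAMES = FALSE)
  known <- classes != "UNKNOWN"
  structure(list(
    doc_id = doc$doc_id,
    rows_seen = length(rows),
    classified = sort(unique(classes[known])),
    unknown_terms = sort(unique(terms[!known & nzchar(terms)])),
    meds_found = length(regions) > 0L && any(known)
  ), class = "cardext_meds")
}

#' Extract discharge medications for a whole corpus
#'
#' @param docs List of \code{cardext_summary} objects.
#' @param dictionary A \code{cardext_meddict}, loaded once for the corpus.
#' @param ... Passed to \code{\link{extract_patient_medications}}.
#' @return List of \code{cardext_meds}, one per document.
#' @export
extract_corpus_medications <- function(docs,
                                       dictionary = load_medication_dictionary(),
                                       ...) {
  cache <- new.env(parent = emptyenv())
  lapply(docs, extract_patient_medications, dictionary = dictionary,
         .class_cache = cache, ...)
}

#' Binary document-by-drug-class indicator matrix
#'
#' @param results List of \code{cardext_meds} objects.
#' @return data.frame with \code{doc_id}, \code{meds_found} and one logical
#'   column per drug class (names prefixed \code{med_}).
#' @export
medication_matrix <- function(results) {
  cols <- paste0("med_", DRUG_CLASSES)
  mat <- matrix(FALSE, nrow = length(results), ncol = length(DRUG_CLASSES),
                dimnames = list(NULL, cols))
  for (i in seq_along(results)) {
    mat[i, match(results[[i]]$classified, DRUG_CLASSES)] <- TRUE
  }
  out <- data.frame(
    doc_id = vapply(results, `[[`, "", "doc_id"),
    meds_found = vapply(results, `[[`, FALSE, "meds_found"),
    mat, stringsAsFactors = FALSE, check.names = FALSE
  )
  attr(out, "class_names") <- stats::setNames(cols, DRUG_CLASSES)
  out
}

#' Frequency report of unclassified base terms
#'
#' Aggregates \code{unknown_terms} across a corpus for the manual-labeling
#' workflow.
#'
#' @param results List of \code{cardext_meds} objects.
#' @return data.frame with \code{term} and \code{frequency} (document count),
#'   sorted by decreasing frequency.
#' @export
unknown_terms_report <- function(results) {
  terms <- unlist(lapply(results, `[[`, "unknown_terms"), use.names = FALSE)
  if (!length(terms))
    return(data.frame(term = character(0), frequency = integer(0)))
  tab <- sort(table(terms), decreasing = TRUE)
  data.frame(term = names(tab), frequency = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
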