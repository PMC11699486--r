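# Closed set of drug classes modeled by the medication extractor. Everything
# else (diuretics, anticoagulants, PPIs, ...) classifies as UNKNOWN.
DRUG_CLASSES <- c(
  "aspirin", "statin", "clopidogrel", "beta_blocker", "antidiabetic",
  "ace_inhibitor", "arb", "aspirin_clopidogrel_combo", "ticagrelor"
)

#' Drug classes recognized by the medication extractor
#'
#' The nine therapeutic classes modeled for discharge-medication analysis
#' (ATC-derived groupings relevant to post-infarction care). Any medication
#' outside this set is reported as \code{"UNKNOWN"} and queued for manual
#' labeling.
#'
#' @return Character vector of the nine class labels.
#' @export
drug_classes <- function() DRUG_CLASSES

#' Normalize a clinical term
#'
#' Lowercases, folds accented characters to ASCII where possible, replaces
#' punctuation with spaces and collapses runs of whitespace. Idempotent:
#' \code{normalize_term(normalize_term(x)) == normalize_term(x)}.
#'
#' @param raw Character vector of raw terms.
#' @return Character vector of normalized terms ("" for empty input).
#' @examples
#' normalize_term("Chest Pain,")              # "chest pain"
#' normalize_term("SOB—Shortness of Breath")
#' @export
normalize_term <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- tolower(x)
  nonascii <- grepl("[^\x01-\x7f]", x)
  if (any(nonascii)) {
    folded <- suppressWarnings(iconv(x[nonascii], from = "UTF-8",
                                     to = "ASCII//TRANSLIT"))
    x[nonascii] <- ifelse(is.na(folded), x[nonascii], folded)
  }
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

# ---- symptom lexicon --------------------------------------------------------

new_symptom_concept <- function(canonical, synonyms) {
  canonical <- normalize_term(canonical)
  synonyms <- unique(normalize_term(synonyms))
  synonyms <- synonyms[nzchar(synonyms)]
  if (!nzchar(canonical))
    stop("symptom concept must have a non-empty canonical name", call. = FALSE)
  if (!canonical %in% synonyms) synonyms <- c(canonical, synonyms)
  structure(
    list(
      canonical_name = canonical,
      synonyms = synonyms,
      multiword = max(lengths(strsplit(synonyms, " ", fixed = TRUE))) > 1L
    ),
    class = "cardext_concept"
  )
}

validate_lexicon <- function(concepts) {
  canon <- vapply(concepts, `[[`, "", "canonical_name")
  dup <- canon[duplicated(canon)]
  if (length(dup))
    stop("duplicate canonical name(s) in lexicon: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  structure(concepts, class = "cardext_lexicon")
}

#' Load a symptom lexicon
#'
#' Reads a JSON lexicon (an array of \code{{"canonical": str, "synonyms":
#' [str]}} objects) or returns the builtin lexicon shipped with the package.
#' The builtin set covers the 18 canonical presenting symptoms of acute
#' myocardial infarction tracked by the extractor, including the Urdu
#' loanword "ghabrahat", each with common-sense synonyms. All synonyms are
#' normalized with \code{\link{normalize_term}}.
#'
#' @param source Path to a JSON lexicon file, or \code{"builtin"} (default).
#' @return A \code{cardext_lexicon}: list of concepts, each with
#'   \code{canonical_name}, \code{synonyms} and \code{multiword}.
#' @export
load_symptom_lexicon <- function(source = "builtin") {
  if (identical(source, "builtin"))
    source <- system.file("extdata", "symptom_lexicon.json", package = "cardext",
                          mustWork = TRUE)
  raw <- tryCatch(jsonlite::read_json(source, simplifyVector = FALSE),
                  error = function(e)
                    stop("failed to parse lexicon file '", source, "': ",
                         conditionMessage(e), call. = FALSE))
  concepts <- lapply(raw, function(entry) {
    if (is.null(entry$canonical) || is.null(entry$synonyms))
      stop("lexicon entry missing 'canonical' or 'synonyms' field", call. = FALSE)
    new_symptom_concept(entry$canonical, unlist(entry$synonyms))
  })
  validate_lexicon(concepts)
}

#' @export
print.cardext_lexicon <- function(x, ...) {
  cat("<symptom lexicon>", length(x), "concepts,",
      sum(lengths(lapply(x, `[[`, "synonyms"))), "synonyms\n")
  invisible(x)
}

#' Serialize a symptom lexicon to JSON
#'
#' Inverse of \code{\link{load_symptom_lexicon}}; loading the written file
#' reproduces the concept set exactly.
#'
#' @param lexicon A \code{cardext_lexicon}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_symptom_lexicon <- function(lexicon, path) {
  out <- lapply(lexicon, function(cc)
    list(canonical = cc$canonical_name, synonyms = cc$synonyms))
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

lexicon_canonicals <- function(lexicon)
  vapply(lexicon, `[[`, "", "canonical_name")

# Flat synonym table used by the matcher: one row per synonym.
lexicon_synonym_table <- function(lexicon) {
  syn <- lapply(lexicon, `[[`, "synonyms")
  data.frame(
    concept = rep(lexicon_canonicals(lexicon), lengths(syn)),
    synonym = unlist(syn, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# ---- medication dictionary --------------------------------------------------

#' Load a medication dictionary
#'
#' Reads a CSV with header \code{name,class} mapping medication names (brand
#' or generic) to one of the nine recognized drug classes, or returns the
#' builtin dictionary, which covers generic and Pakistani brand exemplars for
#' every class. Names are normalized; unknown class labels are rejected.
#'
#' @param source Path to a CSV file, or \code{"builtin"} (default).
#' @return A data.frame with columns \code{name}, \code{class}, \code{source}
#'   (class \code{cardext_meddict}).
#' @export
load_medication_dictionary <- function(source = "builtin") {
  if (identical(source, "builtin"))
    source <- system.file("extdata", "medication_dictionary.csv",
                          package = "cardext", mustWork = TRUE)
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) {
    empty <- data.frame(name = character(0), class = character(0),
                        source = character(0), stringsAsFactors = FALSE)
    class(empty) <- c("cardext_meddict", "data.frame")
    return(empty)
  }
  if (!all(c("name", "class") %in% names(df)))
    stop("medication dictionary must have columns 'name' and 'class'",
         call. = FALSE)
  bad <- setdiff(unique(df$class), DRUG_CLASSES)
  if (length(bad))
    stop("unknown drug class label(s): ", paste(bad, collapse = ", "),
         "; permitted classes: ", paste(DRUG_CLASSES, collapse = ", "),
         call. = FALSE)
  df$name <- normalize_term(df$name)
  if (anyDuplicated(df$name))
    stop("duplicate medication name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  if (is.null(df$source)) df$source <- "dictionary"
  df <- df[order(df$name), c("name", "class", "source")]
  rownames(df) <- NULL
  class(df) <- c("cardext_meddict", "data.frame")
  df
}

# ---- negation configuration -------------------------------------------------

#' Negation-detection configuration
#'
#' A symptom mention is flagged negated when one of \code{cue_terms} occurs
#' among the \code{window_tokens} tokens immediately preceding it, without
#' crossing a sentence boundary (".", ";" or newline) when
#' \code{sentence_bounded}.
#'
#' @param cue_terms Lowercase negation cues. The default extends the classic
#'   "no"/"not" pair with common denial verbs seen in discharge narratives.
#' @param window_tokens Look-back window size in tokens (>= 1).
#' @param sentence_bounded Stop the look-back at sentence boundaries.
#' @return A \code{cardext_negation} configuration list.
#' @export
negation_config <- function(cue_terms = c("no", "not", "denies", "denied",
                                          "without", "nil"),
                            window_tokens = 3L,
                            sentence_bounded = TRUE) {
  cue_terms <- unique(normalize_term(cue_terms))
  cue_terms <- cue_terms[nzchar(cue_terms)]
  if (!length(cue_terms)) stop("cue set must be non-empty", call. = FALSE)
  window_tokens <- as.integer(window_tokens)
  if (is.na(window_tokens) || window_tokens < 1L)
    stop("window_tokens must be >= 1", call. = FALSE)
  structure(list(cue_terms = cue_terms, window_tokens = window_tokens,
                 sentence_bounded = isTRUE(sentence_bounded)),
            class = "cardext_negation")
}
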