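# Fuzzy presenting-symptom extraction: normalized-Levenshtein phrase matching
# over token windows, with preceding-window negation detection.

BOUNDARY_TOKENS <- c(".", ";", "\n")

EMPTY_MATCHES <- data.frame(
  concept = character(0), matched_text = character(0),
  similarity = numeric(0), negated = logical(0),
  token_start = integer(0), token_end = integer(0),
  stringsAsFactors = FALSE
)

#' Tokenize clinical text for matching
#'
#' Lowercases and ASCII-folds the text, maps punctuation to spaces but keeps
#' sentence boundaries (".", ";", newline) as standalone tokens so negation
#' scope can respect them.
#'
#' @param text Character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_clinical <- function(text) {
  stopifnot(length(text) == 1L)
  x <- tolower(as.character(text))
  if (grepl("[^\x01-\x7f]", x)) {
    folded <- suppressWarnings(iconv(x, from = "UTF-8",
                                     to = "ASCII//TRANSLIT"))
    if (!is.na(folded)) x <- folded
  }
  x <- gsub("\n", " \n ", x, fixed = TRUE)
  x <- gsub("([.;])", " \\1 ", x)
  x <- gsub("[^a-z0-9.;\n]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks[nzchar(toks)]
}

#' Normalized Levenshtein similarity on a 0-100 scale
#'
#' \code{100 * (1 - LEV(a, b) / max(nchar(a), nchar(b)))}, where LEV is
#' unit-cost character-level edit distance. Two empty strings score 100.
#' Symmetric; equals 100 iff the strings are identical.
#'
#' @param a,b Character vectors (recycled to common length), assumed
#'   pre-normalized.
#' @return Numeric vector of similarities in [0, 100].
#' @examples
#' similarity("chst pain", "chest pain")  # 90
#' similarity("pain", "gain")             # 75
#' @export
similarity <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(numeric(0))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- vapply(seq_len(n), function(i) utils::adist(a[i], b[i])[1, 1], 0)
  mx <- pmax(nchar(a), nchar(b))
  ifelse(mx == 0L, 100, 100 * (1 - d / mx))
}

# Similarity of every window string against every synonym string (matrix),
# via a single vectorized adist call per invocation.
similarity_matrix <- function(windows, synonyms) {
  d <- utils::adist(windows, synonyms)
  mx <- outer(nchar(windows), nchar(synonyms), pmax)
  s <- 100 * (1 - d / mx)
  s[mx == 0L] <- 100
  s
}

#' Detect negation of a token-window match
#'
#' True iff a negation cue occurs among the \code{window_tokens} tokens
#' immediately preceding the match, without crossing a sentence boundary
#' (".", ";", newline token) when \code{sentence_bounded}.
#'
#' @param tokens Token vector (as from \code{\link{tokenize_clinical}}).
#' @param match_start 0-based index of the first matched token.
#' @param config A \code{\link{negation_config}}.
#' @return Logical scalar.
#' @export
detect_negation <- function(tokens, match_start, config = negation_config()) {
  stopifnot(match_start >= 0, match_start < length(tokens))
  pos <- match_start        # 0-based; R index of match head is pos + 1
  looked <- 0L
  i <- pos                  # R index of token immediately preceding the match
  while (i >= 1L && looked < config$window_tokens) {
    tok <- tokens[i]
    if (tok %in% BOUNDARY_TOKENS) {
      if (config$sentence_bounded) return(FALSE)
      i <- i - 1L
      next                  # boundaries don't consume window when unbounded
    }
    if (tok %in% config$cue_terms) return(TRUE)
    looked <- looked + 1L
    i <- i - 1L
  }
  FALSE
}

#' Fuzzy-match symptom concepts in a passage
#'
#' For each lexicon synonym of k tokens, slides a k-token window over the
#' passage tokens (windows never span sentence-boundary tokens), scores the
#' space-joined window against the synonym with \code{\link{similarity}}, and
#' emits a match when the score meets \code{threshold} (inclusive).
#' Overlapping windows hitting the same concept are merged into the single
#' highest-scoring match (ties: earliest window). Each emitted match carries
#' a negation flag from \code{\link{detect_negation}}.
#'
#' @param passage A \code{cardext_passage} or character scalar.
#' @param lexicon A \code{cardext_lexicon}.
#' @param threshold Similarity threshold in (0, 100]; default 80.
#' @param negation A \code{\link{negation_config}}.
#' @return data.frame with columns \code{concept}, \code{matched_text},
#'   \code{similarity}, \code{negated}, \code{token_start}, \code{token_end}
#'   (0-based, half-open token indices).
#' @export
match_symptoms <- function(passage, lexicon, threshold = 80,
                           negation = negation_config()) {
  stopifnot(threshold > 0, threshold <= 100)
  empty <- EMPTY_MATCHES
  if (!length(lexicon)) {
    warning("empty symptom lexicon: no matches possible")
    return(empty)
  }
  text <- if (inherits(passage, "cardext_passage")) passage$text else passage
  tokens <- tokenize_clinical(text)
  if (!length(tokens)) return(empty)
  syn <- attr(lexicon, "syn_table")
  if (is.null(syn)) {
    syn <- lexicon_synonym_table(lexicon)
    syn$k <- lengths(strsplit(syn$synonym, " ", fixed = TRUE))
  }
  nt <- length(tokens)
  is_bound <- tokens %in% BOUNDARY_TOKENS
  cb <- c(0L, cumsum(is_bound))
  h_concept <- h_text <- character(0)
  h_sim <- numeric(0)
  h_start <- h_end <- integer(0)
  for (k in sort(unique(syn$k))) {
    if (k > nt) next
    ns <- nt - k + 1L
    starts <- seq_len(ns)
    # exclude windows containing a sentence-boundary token
    keep <- (cb[starts + k] - cb[starts]) == 0L
    starts <- starts[keep]
    if (!length(starts)) next
    wins <- tokens[starts]
    if (k > 1L) for (j in seq_len(k - 1L))
      wins <- paste(wins, tokens[starts + j])
    ski <- which(syn$k == k)
    sim <- similarity_matrix(wins, syn$synonym[ski])
    idx <- which(sim >= threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      h_concept <- c(h_concept, syn$concept[ski[idx[, 2]]])
      h_text <- c(h_text, wins[idx[, 1]])
      h_sim <- c(h_sim, sim[idx])
      h_start <- c(h_start, starts[idx[, 1]] - 1L)   # to 0-based
      h_end <- c(h_end, starts[idx[, 1]] - 1L + k)
    }
  }
  if (!length(h_concept)) return(empty)
  # merge transitively overlapping windows per concept, keep best score
  # (ties: earliest window)
  ord <- order(h_concept, h_start, h_end)
  keep_idx <- integer(0)
  cur_best <- 0L; cur_concept <- ""; reach <- -1L
  for (i in ord) {
    if (h_concept[i] != cur_concept || h_start[i] >= reach) {
      if (cur_best) keep_idx <- c(keep_idx, cur_best)
      cur_best <- i; cur_concept <- h_concept[i]; reach <- h_end[i]
    } else {
      reach <- max(reach, h_end[i])
      if (h_sim[i] > h_sim[cur_best]) cur_best <- i
    }
  }
  if (cur_best) keep_idx <- c(keep_idx, cur_best)
  keep_idx <- keep_idx[order(h_start[keep_idx], h_concept[keep_idx])]
  structure(list(
    concept = h_concept[keep_idx],
    matched_text = h_text[keep_idx],
    similarity = h_sim[keep_idx],
    negated = vapply(h_start[keep_idx], function(s)
      detect_negation(tokens, s, negation), FALSE),
    token_start = h_start[keep_idx],
    token_end = h_end[keep_idx]
  ), class = "data.frame", row.names = seq_along(keep_idx))
}

#' Extract presenting symptoms for one discharge summary
#'
#' Composes passage location (\code{\link{extract_presenting_passage}}),
#' fuzzy matching (\code{\link{match_symptoms}}) and negation handling. A
#' concept is present when it has at least one non-negated match in the
#' presenting passage.
#'
#' @param doc A \code{cardext_summary}.
#' @param lexicon A \code{cardext_lexicon}; default builtin.
#' @param threshold Similarity threshold (default 80, inclusive).
#' @param negation A \code{\link{negation_config}}.
#' @param patterns,presenting,triggers Passage-location configuration.
#' @return A \code{cardext_extraction}: list with \code{doc_id},
#'   \code{matches} (data.frame), \code{symptoms_present} (character vector of
#'   canonical names), \code{passage_found} (logical).
#' @export
extract_patient_symptoms <- function(doc,
                                     lexicon = load_symptom_lexicon(),
                                     threshold = 80,
                                     negation = negation_config(),
                                     patterns = heading_patterns(),
                                     presenting = presenting_heading_patterns(),
                                     triggers = trigger_phrases()) {
  passage <- extract_presenting_passage(doc, patterns, presenting, triggers)
  if (is.null(passage)) {
    matches <- match_symptoms("", lexicon, threshold, negation)
    return(structure(list(doc_id = doc$doc_id, matches = matches,
                          symptoms_present = character(0),
                          passage_found = FALSE),
                     class = "cardext_extraction"))
  }
  matches <- match_symptoms(passage, lexicon, threshold, negation)
  present <- unique(matches$concept[!matches$negated])
  structure(list(doc_id = doc$doc_id, matches = matches,
                 symptoms_present = sort(present), passage_found = TRUE),
            class = "cardext_extraction")
}

#' Extract presenting symptoms for a whole corpus
#'
#' @param docs List of \code{cardext_summary} objects.
#' @param lexicon A \code{cardext_lexicon}; loaded (and its synonym table
#'   compiled) once for the whole corpus.
#' @param ... Passed to \code{\link{extract_patient_symptoms}}.
#' @return List of \code{cardext_extraction}, one per document.
#' @export
extract_corpus_symptoms <- function(docs, lexicon = load_symptom_lexicon(),
                                    ...) {
  syn <- lexicon_synonym_table(lexicon)
  syn$k <- lengths(strsplit(syn$synonym, " ", fixed = TRUE))
  attr(lexicon, "syn_table") <- syn
  lapply(docs, extract_patient_symptoms, lexicon = lexicon, ...)
}

#' Binary document-by-symptom indicator matrix
#'
#' @param results List of \code{cardext_extraction} objects.
#' @param lexicon Lexicon defining the column set.
#' @return data.frame with \code{doc_id}, \code{passage_found} and one logical
#'   column per canonical symptom (names prefixed \code{sym_}, spaces as
#'   underscores).
#' @export
symptom_matrix <- function(results, lexicon = load_symptom_lexicon()) {
  canon <- lexicon_canonicals(lexicon)
  cols <- paste0("sym_", gsub(" ", "_", canon, fixed = TRUE))
  mat <- matrix(FALSE, nrow = length(results), ncol = length(canon),
                dimnames = list(NULL, cols))
  for (i in seq_along(results)) {
    present <- results[[i]]$symptoms_present
    mat[i, match(present, canon)] <- TRUE
  }
  out <- data.frame(
    doc_id = vapply(results, `[[`, "", "doc_id"),
    passage_found = vapply(results, `[[`, FALSE, "passage_found"),
    mat, stringsAsFactors = FALSE, check.names = FALSE
  )
  attr(out, "symptom_names") <- stats::setNames(cols, canon)
  out
}
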