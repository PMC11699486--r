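# Independent oracles, implemented without touching the package's own
# similarity / matching code paths.

# Unit-cost Levenshtein distance by the classic dynamic-programming matrix.
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(
        D[i, j + 1] + 1L,
        D[i + 1, j] + 1L,
        D[i, j] + (x[i] != y[j])
      )
    }
  }
  D[n + 1, m + 1]
}

# Similarity score recomputed from the DP oracle.
sim_oracle <- function(a, b) {
  mx <- max(nchar(a), nchar(b))
  if (mx == 0) return(100)
  100 * (1 - lev_dp(a, b) / mx)
}

# Brute-force window matcher: exhaustively scores every k-token window of the
# passage against every synonym, no merging shortcuts. Returns the set of
# (concept, token_start) pairs whose best cluster representative survives,
# mirroring the contract: concept present iff some window scores >= threshold.
brute_force_concepts <- function(text, lexicon, threshold) {
  toks <- tokenize_clinical(text)
  bound <- toks %in% c(".", ";", "\n")
  hits <- character(0)
  for (concept in vapply(lexicon, `[[`, "", "canonical_name")) {
    syns <- lexicon[[which(vapply(lexicon, `[[`, "", "canonical_name") ==
                             concept)]]$synonyms
    for (s in syns) {
      k <- length(strsplit(s, " ", fixed = TRUE)[[1]])
      if (k > length(toks)) next
      for (st in seq_len(length(toks) - k + 1L)) {
        idx <- st:(st + k - 1L)
        if (any(bound[idx])) next
        w <- paste(toks[idx], collapse = " ")
        if (sim_oracle(w, s) >= threshold) hits <- c(hits, concept)
      }
    }
  }
  sort(unique(hits))
}

# Pearson chi-square by explicit expected-count summation.
chisq_oracle <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

make_doc <- function(text, doc_id = "d1", gender = "woman", age = 60,
                     year = 2015, diabetes = FALSE, pci = FALSE) {
  discharge_summary(doc_id, text, gender, age, year, diabetes, pci)
}

# Tiny two-concept lexicon written through the public file interface.
tiny_lexicon <- function(concepts = list(
    list(canonical = "chest pain",
         synonyms = c("chest pain", "chest discomfort")),
    list(canonical = "shortness of breath",
         synonyms = c("shortness of breath", "sob")))) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(concepts, f, auto_unbox = TRUE)
  load_symptom_lexicon(f)
}
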