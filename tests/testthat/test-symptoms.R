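test_that("similarity matches the DP edit-distance oracle", {
  cases <- list(c("chest pain", "chest pain"), c("chst pain", "chest pain"),
                c("pain", "gain"), c("chest pian", "chest pain"),
                c("", ""), c("", "abc"), c("kitten", "sitting"))
  for (cs in cases)
    expect_equal(similarity(cs[1], cs[2]), sim_oracle(cs[1], cs[2]))
  expect_equal(similarity("chest pain", "chest pain"), 100)
  expect_equal(similarity("chst pain", "chest pain"), 90)
  expect_equal(similarity("pain", "gain"), 75)
  expect_equal(similarity("", ""), 100)
})

test_that("similarity is symmetric, bounded, 100 iff equal (random strings)", {
  set.seed(31)
  for (i in 1:200) {
    a <- paste(sample(letters[1:6], sample(0:8, 1), TRUE), collapse = "")
    b <- paste(sample(letters[1:6], sample(0:8, 1), TRUE), collapse = "")
    s <- similarity(a, b)
    expect_equal(s, similarity(b, a))
    expect_gte(s, 0); expect_lte(s, 100)
    expect_identical(s == 100, a == b)
    expect_equal(s, sim_oracle(a, b))
  }
})

test_that("match_symptoms finds fuzzy and exact hits at the threshold", {
  lex <- tiny_lexicon(list(
    list(canonical = "chest pain",
         synonyms = c("chest pain", "chest discomfort")),
    list(canonical = "sweating or diaphoresis",
         synonyms = c("sweating", "diaphoresis"))))
  m <- match_symptoms("complained of chest pian and sweating", lex)
  expect_setequal(m$concept, c("chest pain", "sweating or diaphoresis"))
  expect_equal(m$similarity[m$concept == "chest pain"], 80)
  expect_equal(m$matched_text[m$concept == "chest pain"], "chest pian")
  expect_equal(m$similarity[m$concept == "sweating or diaphoresis"], 100)

  m2 <- match_symptoms("no chest pain", lex)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$similarity, 100)
  expect_true(m2$negated)

  expect_equal(nrow(match_symptoms("unremarkable exam", lex)), 0L)
  expect_warning(m3 <- match_symptoms("chest pain", list()), "empty")
  expect_equal(nrow(m3), 0L)
})

test_that("overlapping windows on one concept merge to the best match", {
  lex <- tiny_lexicon(list(
    list(canonical = "chest pain",
         synonyms = c("chest pain", "chest pains"))))
  m <- match_symptoms("severe chest pain today", lex)
  expect_equal(nrow(m), 1L)
  expect_equal(m$similarity, 100)
  expect_equal(m$matched_text, "chest pain")
  expect_lt(m$token_start, m$token_end)
})

test_that("matcher equals the brute-force oracle on random passages", {
  lex <- tiny_lexicon(list(
    list(canonical = "chest pain", synonyms = c("chest pain")),
    list(canonical = "shortness of breath",
         synonyms = c("shortness of breath", "sob")),
    list(canonical = "sweating or diaphoresis", synonyms = c("sweating"))))
  vocab <- c("chest", "pain", "chst", "pian", "sweating", "sweating", "sob",
             "shortness", "of", "breath", "patient", "the", "with", "no",
             "and", ".", "stable")
  set.seed(77)
  for (i in 1:60) {
    toks <- sample(vocab, sample(3:20, 1), replace = TRUE)
    text <- paste(toks, collapse = " ")
    got <- unique(match_symptoms(text, lex)$concept)
    expect_setequal(got, brute_force_concepts(text, lex, 80))
  }
})

test_that("lowering the threshold never removes a match (monotonicity)", {
  lex <- load_symptom_lexicon()
  passages <- c("complained of chest pian and swaeting",
                "presented with gabrahat and sob",
                "has nauseaa and vomitting with dizzines")
  for (txt in passages) {
    sets <- lapply(c(90, 80, 70), function(th)
      unique(match_symptoms(txt, lex, threshold = th)$concept))
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
  }
})

test_that("detect_negation honors cue set, window and sentence bounds", {
  cfg <- negation_config()
  toks1 <- tokenize_clinical("no chest pain")
  expect_true(detect_negation(toks1, match_start = 1, cfg))
  toks2 <- tokenize_clinical("patient has chest pain")
  expect_false(detect_negation(toks2, match_start = 2, cfg))
  # cue exactly window_tokens before the match head
  toks3 <- tokenize_clinical("not associated with shortness of breath")
  expect_true(detect_negation(toks3, match_start = 3, cfg))
  expect_false(detect_negation(toks3, match_start = 3,
                               negation_config(window_tokens = 2)))
  # sentence boundary blocks the cue
  toks4 <- tokenize_clinical("denies fever. chest pain present")
  expect_false(detect_negation(toks4, match_start = 3, cfg))
  expect_true(detect_negation(
    toks4, match_start = 3,
    negation_config(window_tokens = 4, sentence_bounded = FALSE)))
})

test_that("extract_patient_symptoms composes passage, matching, negation", {
  lex <- load_symptom_lexicon()
  d1 <- make_doc(paste0("PRESENTING COMPLAINTS:\nThe patient presented with ",
                        "ghabrahat and shortness of breath."))
  r1 <- extract_patient_symptoms(d1, lex)
  expect_true(r1$passage_found)
  expect_setequal(r1$symptoms_present, c("ghabrahat", "shortness of breath"))

  d2 <- make_doc("The patient complained of no chest pain, has sob today.")
  r2 <- extract_patient_symptoms(d2, lex)
  expect_setequal(r2$symptoms_present, "shortness of breath")
  cp <- r2$matches[r2$matches$concept == "chest pain", ]
  expect_equal(nrow(cp), 1L)
  expect_true(cp$negated)

  d3 <- make_doc("HOSPITAL COURSE:\nuneventful")
  r3 <- extract_patient_symptoms(d3, lex)
  expect_false(r3$passage_found)
  expect_length(r3$symptoms_present, 0L)
})

test_that("negated-only concepts never enter symptoms_present (corpus-wide)", {
  gen <- generate_corpus(synth_config(150, seed = 300, negation_rate = 0.5))
  res <- extract_corpus_symptoms(gen$docs)
  for (r in res) {
    neg_only <- setdiff(unique(r$matches$concept[r$matches$negated]),
                        unique(r$matches$concept[!r$matches$negated]))
    expect_length(intersect(neg_only, r$symptoms_present), 0L)
  }
})

test_that("symptom_matrix lays out one logical column per concept", {
  lex <- load_symptom_lexicon()
  docs <- list(
    make_doc("Presenting Complaints: chest pain and sweating.", "a"),
    make_doc("HOSPITAL COURSE:\nnothing", "b"))
  sm <- symptom_matrix(extract_corpus_symptoms(docs, lexicon = lex), lex)
  expect_equal(nrow(sm), 2L)
  expect_equal(ncol(sm), 2L + 18L)
  expect_true(sm$sym_chest_pain[1])
  expect_false(sm$passage_found[2])
  expect_false(any(as.logical(sm[2, -(1:2)])))
})
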