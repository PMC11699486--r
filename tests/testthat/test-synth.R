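test_that("generate_corpus: count, determinism, forced prevalence", {
  cfg <- synth_config(10, seed = 42)
  gen <- generate_corpus(cfg)
  expect_length(gen$docs, 10L)
  expect_equal(nrow(gen$truth), 10L)
  gen2 <- generate_corpus(cfg)
  expect_identical(vapply(gen$docs, `[[`, "", "text"),
                   vapply(gen2$docs, `[[`, "", "text"))
  expect_identical(gen$truth, gen2$truth)

  sp <- default_symptom_prevalence()
  sp$woman[sp$symptom == "chest pain"] <- 1
  sp$man[sp$symptom == "chest pain"] <- 1
  forced <- generate_corpus(synth_config(
    30, seed = 7, symptom_prevalence = sp, typo_rate = 0,
    passage_prob = c(woman = 1, man = 1)))
  expect_true(all(vapply(forced$truth$true_symptoms,
                         function(s) "chest pain" %in% s, FALSE)))
})

test_that("synth_config validates probabilities and template weights", {
  expect_error(synth_config(0), "positive integer")
  expect_error(synth_config(5, prop_women = 1.2), "probabilities")
  expect_error(synth_config(5, typo_rate = -0.1), "probabilities")
  expect_error(synth_config(5, template_mix = c(heading = -1, table = 2)),
               "non-negative")
  cfg <- synth_config(5, template_mix = c(heading = 2, narrative = 2))
  expect_equal(sum(cfg$template_mix), 1)
})

test_that("inject_typo always lands at edit distance exactly 1", {
  expect_equal(inject_typo("a"), "a")
  set.seed(99)
  words <- c("chest", "pain", "sweating", "ab", "ghabrahat")
  for (i in 1:2000) {
    w <- sample(words, 1)
    out <- inject_typo(w)
    expect_equal(lev_dp(w, out), 1L)
    expect_true(abs(nchar(out) - nchar(w)) <= 1)
  }
})

test_that("ground-truth prevalences converge to configuration", {
  n <- 5000
  gen <- generate_corpus(synth_config(n, seed = 2024,
                                      passage_prob = c(woman = 1, man = 1)))
  sp <- default_symptom_prevalence()
  for (g in c("woman", "man")) {
    rows <- gen$truth$gender == g
    ng <- sum(rows)
    for (s in c("chest pain", "shortness of breath", "ghabrahat")) {
      p <- sp[[g]][sp$symptom == s]
      obs <- mean(vapply(gen$truth$true_symptoms[rows],
                         function(x) s %in% x, FALSE))
      se <- sqrt(p * (1 - p) / ng)
      expect_lt(abs(obs - p), 3 * se + 1e-9)
    }
  }
})

test_that("negated mentions never overlap true symptoms", {
  gen <- generate_corpus(synth_config(400, seed = 5, negation_rate = 0.5))
  overlap <- mapply(function(t, n) length(intersect(t, n)),
                    gen$truth$true_symptoms, gen$truth$negated_mentions)
  expect_true(all(overlap == 0))
  expect_gt(sum(lengths(gen$truth$negated_mentions)), 0)
})

test_that("evaluate_extraction scores sets correctly", {
  gen <- generate_corpus(synth_config(30, seed = 8, typo_rate = 0,
                                      negation_rate = 0))
  res <- extract_corpus_symptoms(gen$docs)
  perfect <- lapply(seq_len(nrow(gen$truth)), function(i)
    structure(list(doc_id = gen$truth$doc_id[i],
                   symptoms_present = gen$truth$true_symptoms[[i]],
                   passage_found = TRUE), class = "cardext_extraction"))
  ev <- evaluate_extraction(gen$truth, perfect, "symptoms")
  expect_equal(ev$micro$precision, 1)
  expect_equal(ev$micro$recall, 1)

  nothing <- lapply(perfect, function(r) {
    r$symptoms_present <- character(0); r })
  ev0 <- evaluate_extraction(gen$truth, nothing, "symptoms")
  expect_equal(ev0$micro$recall, 0)
  expect_equal(ev0$micro$precision, 1)  # vacuous: no predictions

  bad <- perfect
  bad[[1]]$doc_id <- "ghost"
  expect_error(evaluate_extraction(gen$truth, bad), "same doc_ids")
})

test_that("typo monotonicity: micro recall non-increasing in typo rate", {
  recalls <- vapply(c(0, 0.1, 0.3), function(tr) {
    gen <- generate_corpus(synth_config(300, seed = 123, typo_rate = tr,
                                        negation_rate = 0))
    ev <- evaluate_extraction(gen$truth,
                              extract_corpus_symptoms(gen$docs), "symptoms")
    ev$micro$recall
  }, 0)
  expect_true(all(diff(recalls) <= 1e-9))
  expect_equal(recalls[1], 1)
})

test_that("truth JSONL round-trips", {
  gen <- generate_corpus(synth_config(15, seed = 33))
  f <- tempfile(fileext = ".jsonl")
  write_truth(gen$truth, f)
  back <- read_truth(f)
  expect_equal(back$doc_id, gen$truth$doc_id)
  expect_equal(back$true_symptoms, gen$truth$true_symptoms)
  expect_equal(back$true_classes, gen$truth$true_classes)
  expect_equal(back$negated_mentions, gen$truth$negated_mentions)
})

test_that("medication ground truth matches extraction on clean corpora", {
  gen <- generate_corpus(synth_config(200, seed = 61, typo_rate = 0))
  ev <- evaluate_extraction(gen$truth,
                            extract_corpus_medications(gen$docs),
                            "medications")
  expect_equal(ev$micro$precision, 1)
  expect_equal(ev$micro$recall, 1)
})
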