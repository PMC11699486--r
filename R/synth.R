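# Synthetic discharge-summary generator with known ground truth. The
# defaults encode the published cohort: per-gender symptom prevalences among
# symptomatic admissions, medication-class prevalences recovered from overall
# frequencies and univariate odds ratios, and cohort composition (1769 women,
# 3589 men; 1061/2278 with a documented presenting complaint).

#' Default per-gender symptom prevalences
#'
#' Prevalences among admissions with a documented presenting complaint
#' (denominators: 1061 women, 2278 men).
#'
#' @return data.frame with columns \code{symptom}, \code{woman}, \code{man}.
#' @export
default_symptom_prevalence <- function() {
  counts <- rbind(
    c("chest pain",               597, 1567),
    c("shortness of breath",      525,  859),
    c("nausea or vomiting",       105,  124),
    c("sweating or diaphoresis",   58,  167),
    c("abdominal pain",            83,  107),
    c("arm pain",                  36,   91),
    c("ghabrahat",                 54,   84),
    c("weakness",                  38,   57),
    c("shoulder pain",             30,   63),
    c("palpitations",              28,   43),
    c("back pain",                 23,   36),
    c("altered mental status",     15,   42),
    c("dizziness",                 14,   29),
    c("jaw pain",                  15,   14),
    c("orthopnea",                 14,   18),
    c("neck pain",                  7,    9),
    c("throat pain",                0,    4),
    c("swelling",                   1,    0)
  )
  data.frame(symptom = counts[, 1],
             woman = as.numeric(counts[, 2]) / 1061,
             man = as.numeric(counts[, 3]) / 2278,
             stringsAsFactors = FALSE)
}

# Solve per-gender probabilities (p_w, p_m) from an overall prevalence P,
# a women-vs-men odds ratio r and the women fraction w of the denominator.
solve_gender_probs <- function(P, r, w) {
  p_w_of <- function(p_m) {
    q <- r * p_m / (1 - p_m)
    q / (1 + q)
  }
  f <- function(p_m) w * p_w_of(p_m) + (1 - w) * p_m - P
  p_m <- stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  c(woman = p_w_of(p_m), man = p_m)
}

#' Default per-gender medication-class prevalences
#'
#' Among admissions with a detected discharge-medication table. Per-gender
#' values are recovered from the overall class prevalences and the
#' univariate women-vs-men odds ratios, assuming the women fraction of the
#' medication denominator matches the cohort (1769/5358).
#'
#' @param women_fraction Women fraction of the medication denominator.
#' @return data.frame with columns \code{class}, \code{woman}, \code{man}.
#' @export
default_medication_prob <- function(women_fraction = 1769 / 5358) {
  spec <- rbind(
    c("aspirin",                   4070, 0.86),
    c("statin",                    3962, 0.62),
    c("clopidogrel",               3659, 0.69),
    c("beta_blocker",              3405, 0.62),
    c("antidiabetic",              1795, 1.51),
    c("ace_inhibitor",             1685, 0.75),
    c("arb",                        546, 1.64),
    c("aspirin_clopidogrel_combo",   38, 1.19),
    c("ticagrelor",                   3, 4.06)
  )
  probs <- t(vapply(seq_len(nrow(spec)), function(i)
    solve_gender_probs(as.numeric(spec[i, 2]) / 4301,
                       as.numeric(spec[i, 3]), women_fraction),
    c(woman = 0, man = 0)))
  data.frame(class = spec[, 1], woman = probs[, "woman"],
             man = probs[, "man"], stringsAsFactors = FALSE)
}

#' Generator configuration
#'
#' The defaults state the emulated world: cohort composition, per-gender
#' symptom prevalences among symptomatic admissions, recovered per-gender
#' medication prevalences, covariate distributions, and document-noise rates
#' (typos, explicit denials, template heterogeneity).
#'
#' @param n_patients Number of documents to generate.
#' @param prop_women Probability a patient is a woman (default 1769/5358).
#' @param symptom_prevalence data.frame (symptom, woman, man) of prevalences
#'   conditional on a documented presenting complaint.
#' @param medication_prob data.frame (class, woman, man) of prevalences
#'   conditional on a detected medication table.
#' @param passage_prob Named probabilities (woman, man) that a summary
#'   contains a presenting-complaint passage (defaults 1061/1769, 2278/3589).
#' @param meds_section_prob Named probabilities (woman, man) that a summary
#'   carries a medication table (default 4301/5358 for both).
#' @param covariate_model List: \code{diabetes}, \code{pci} prevalences,
#'   \code{age_mean} (named, years), \code{age_sd}, \code{year_range}.
#' @param typo_rate Probability each symptom-mention word receives one random
#'   character edit.
#' @param negation_rate Scale for explicit denials: an absent concept is
#'   documented as negated with probability \code{negation_rate * prevalence}.
#' @param template_mix Named weights over document templates
#'   (\code{heading}, \code{narrative}, \code{table}); normalized to sum 1.
#' @param synonym_prob Probability a mention uses a non-canonical synonym.
#' @param unknown_med_prob Probability a medication table carries one
#'   unclassifiable row (e.g. a proton-pump inhibitor).
#' @param seed Integer seed; \code{NULL} leaves the RNG state untouched.
#' @param lexicon Lexicon supplying mention synonyms.
#' @param dictionary Medication dictionary supplying drug names.
#' @return A validated \code{cardext_synth_config}.
#' @export
synth_config <- function(n_patients,
                         prop_women = 1769 / 5358,
                         symptom_prevalence = default_symptom_prevalence(),
                         medication_prob = default_medication_prob(),
                         passage_prob = c(woman = 1061 / 1769,
                                          man = 2278 / 3589),
                         meds_section_prob = c(woman = 4301 / 5358,
                                               man = 4301 / 5358),
                         covariate_model = list(diabetes = 0.55, pci = 0.60,
                                                age_mean = c(woman = 67.8,
                                                             man = 63.3),
                                                age_sd = 12,
                                                year_range = c(2010L, 2018L)),
                         typo_rate = 0.05,
                         negation_rate = 0.05,
                         template_mix = c(heading = 0.5, narrative = 0.3,
                                          table = 0.2),
                         synonym_prob = 0.2,
                         unknown_med_prob = 0.3,
                         seed = NULL,
                         lexicon = load_symptom_lexicon(),
                         dictionary = load_medication_dictionary()) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L)
    stop("n_patients must be a positive integer", call. = FALSE)
  chk01 <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop(nm, " must be probabilities in [0, 1]", call. = FALSE)
  }
  chk01(prop_women, "prop_women"); chk01(typo_rate, "typo_rate")
  chk01(negation_rate, "negation_rate"); chk01(synonym_prob, "synonym_prob")
  chk01(unknown_med_prob, "unknown_med_prob")
  chk01(c(symptom_prevalence$woman, symptom_prevalence$man),
        "symptom_prevalence")
  chk01(c(medication_prob$woman, medication_prob$man), "medication_prob")
  chk01(passage_prob, "passage_prob"); chk01(meds_section_prob,
                                             "meds_section_prob")
  if (any(template_mix < 0) || sum(template_mix) <= 0)
    stop("template_mix weights must be non-negative with positive sum",
         call. = FALSE)
  template_mix <- template_mix / sum(template_mix)
  canon <- lexicon_canonicals(lexicon)
  missing <- setdiff(symptom_prevalence$symptom, canon)
  if (length(missing))
    stop("symptom_prevalence rows not in lexicon: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(
    n_patients = n_patients, prop_women = prop_women,
    symptom_prevalence = symptom_prevalence,
    medication_prob = medication_prob, passage_prob = passage_prob,
    meds_section_prob = meds_section_prob, covariate_model = covariate_model,
    typo_rate = typo_rate, negation_rate = negation_rate,
    template_mix = template_mix, synonym_prob = synonym_prob,
    unknown_med_prob = unknown_med_prob, seed = seed,
    lexicon = lexicon, dictionary = dictionary
  ), class = "cardext_synth_config")
}

#' Inject exactly one random character edit into a word
#'
#' One of substitution, deletion or insertion at a random position, drawing
#' replacement letters from a-z; the result is always at Levenshtein
#' distance 1 from the input. Words shorter than 2 characters are returned
#' unchanged. Uses (and advances) the current RNG stream.
#'
#' @param word Character scalar.
#' @return The edited word.
#' @export
inject_typo <- function(word) {
  if (nchar(word) < 2L) return(word)
  chars <- strsplit(word, "")[[1]]
  op <- sample(c("sub", "del", "ins"), 1L)
  if (op == "sub") {
    i <- sample(length(chars), 1L)
    repl <- sample(setdiff(letters, chars[i]), 1L)
    chars[i] <- repl
  } else if (op == "del") {
    chars <- chars[-sample(length(chars), 1L)]
  } else {
    i <- sample(length(chars) + 1L, 1L)
    chars <- append(chars, sample(letters, 1L), after = i - 1L)
  }
  paste(chars, collapse = "")
}

apply_typos <- function(phrase, typo_rate) {
  if (typo_rate <= 0) return(phrase)
  words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  hit <- stats::runif(length(words)) < typo_rate
  words[hit] <- vapply(words[hit], inject_typo, "")
  paste(words, collapse = " ")
}

render_mention <- function(concept, lexicon_map, synonym_prob, typo_rate) {
  syns <- lexicon_map[[concept]]
  phrase <- if (length(syns) > 1L && stats::runif(1) < synonym_prob)
    sample(syns[-1], 1L) else syns[1]
  apply_typos(phrase, typo_rate)
}

join_list <- function(x) {
  if (length(x) == 1L) return(x)
  paste(paste(x[-length(x)], collapse = ", "), "and", x[length(x)])
}

NEGATION_FRAMES <- c("No %s.", "Denies %s.", "Denied %s.", "There was no %s.")
UNKNOWN_MEDS <- c("omeprazole", "pantoprazole", "lactulose")

render_med_rows <- function(classes, dictionary, unknown_med_prob) {
  by_class <- split(dictionary$name, dictionary$class)
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  rows <- vapply(classes, function(cl) {
    nm <- sample(by_class[[cl]], 1L)
    sprintf("%s %s %dmg %s",
            sample(c("Tab", "Cap"), 1L), cap(nm),
            sample(c(5L, 10L, 20L, 25L, 40L, 75L, 150L), 1L),
            sample(c("OD", "BD", "TDS"), 1L))
  }, "")
  if (stats::runif(1) < unknown_med_prob)
    rows <- c(rows, sprintf("Tab %s 40mg OD",
                            cap(sample(UNKNOWN_MEDS, 1L))))
  rows
}

render_document <- function(template, mentions, neg_mentions, med_rows) {
  pos_sent <- if (length(mentions))
    sprintf("The patient presented with %s.", join_list(mentions))
  else "The patient presented with nonspecific complaints."
  neg_sents <- vapply(neg_mentions, function(m)
    sprintf(sample(NEGATION_FRAMES, 1L), m), "")
  course <- "HOSPITAL COURSE:\nThe patient remained stable during the stay."
  medsec <- if (length(med_rows))
    paste0("DISCHARGE MEDICATIONS:\n", paste(med_rows, collapse = "\n"))
  else "FOLLOW UP:\nCardiology clinic in two weeks."
  body <- switch(template,
    heading = paste0("PRESENTING COMPLAINTS:\n",
                     paste(c(pos_sent, neg_sents), collapse = " ")),
    narrative = paste(c(pos_sent, neg_sents), collapse = " "),
    table = paste0("PRESENTING COMPLAINTS:\n",
                   paste(c(if (length(mentions)) mentions
                           else "Nonspecific complaints",
                           vapply(neg_mentions, function(m)
                             paste("No", m), "")),
                         collapse = "\n"))
  )
  paste("ADMISSION NOTE", body, course, medsec, sep = "\n\n")
}

render_no_passage_document <- function(med_rows) {
  medsec <- if (length(med_rows))
    paste0("DISCHARGE MEDICATIONS:\n", paste(med_rows, collapse = "\n"))
  else "FOLLOW UP:\nCardiology clinic in two weeks."
  paste("ADMISSION NOTE",
        "Transferred from an outside facility; details unavailable.",
        "HOSPITAL COURSE:\nThe patient remained stable during the stay.",
        medsec, sep = "\n\n")
}

#' Generate a synthetic corpus with ground truth
#'
#' For each patient: draws gender, covariates, a presenting-passage flag,
#' true symptoms (at the configured per-gender prevalences), explicit
#' denials of absent symptoms, and discharge-medication classes; renders a
#' document from a sampled template (heading-led passage, trigger-phrase
#' narrative, or one-symptom-per-line table) with typos injected at
#' \code{typo_rate}; and records the matched ground truth. With a fixed seed
#' the output is bitwise reproducible.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with \code{docs} (list of \code{cardext_summary}) and
#'   \code{truth} (data.frame keyed by \code{doc_id} with list columns
#'   \code{true_symptoms}, \code{negated_mentions}, \code{true_classes}).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "cardext_synth_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  n <- config$n_patients
  cm <- config$covariate_model
  gender <- ifelse(stats::runif(n) < config$prop_women, "woman", "man")
  age <- round(pmin(95, pmax(19, stats::rnorm(
    n, mean = cm$age_mean[gender], sd = cm$age_sd))), 1)
  year <- sample(seq(cm$year_range[1], cm$year_range[2]), n, replace = TRUE)
  diabetes <- stats::runif(n) < cm$diabetes
  pci <- stats::runif(n) < cm$pci
  has_passage <- stats::runif(n) < config$passage_prob[gender]
  has_medsec <- stats::runif(n) < config$meds_section_prob[gender]

  sp <- config$symptom_prevalence
  prev <- as.matrix(sp[, c("woman", "man")])
  rownames(prev) <- sp$symptom
  gcol <- ifelse(gender == "woman", 1L, 2L)
  sym_draw <- matrix(stats::runif(n * nrow(prev)), nrow = n) <
    t(prev)[gcol, , drop = FALSE]
  neg_draw <- matrix(stats::runif(n * nrow(prev)), nrow = n) <
    config$negation_rate * t(prev)[gcol, , drop = FALSE]
  colnames(sym_draw) <- colnames(neg_draw) <- sp$symptom

  mp <- config$medication_prob
  mprev <- as.matrix(mp[, c("woman", "man")])
  rownames(mprev) <- mp$class
  med_draw <- matrix(stats::runif(n * nrow(mprev)), nrow = n) <
    t(mprev)[gcol, , drop = FALSE]
  colnames(med_draw) <- mp$class

  lexicon_map <- stats::setNames(lapply(config$lexicon, `[[`, "synonyms"),
                                 lexicon_canonicals(config$lexicon))
  templates <- sample(names(config$template_mix), n, replace = TRUE,
                      prob = config$template_mix)

  docs <- vector("list", n)
  truth_sym <- truth_neg <- truth_med <- vector("list", n)
  ids <- sprintf("doc%06d", seq_len(n))
  for (i in seq_len(n)) {
    syms <- if (has_passage[i]) sp$symptom[sym_draw[i, ]] else character(0)
    negs <- if (has_passage[i])
      sp$symptom[neg_draw[i, ] & !sym_draw[i, ]] else character(0)
    classes <- if (has_medsec[i]) mp$class[med_draw[i, ]] else character(0)
    med_rows <- if (length(classes))
      render_med_rows(classes, config$dictionary, config$unknown_med_prob)
    else character(0)
    if (has_passage[i]) {
      mentions <- vapply(syms, render_mention, "",
                         lexicon_map = lexicon_map,
                         synonym_prob = config$synonym_prob,
                         typo_rate = config$typo_rate)
      neg_mentions <- vapply(negs, render_mention, "",
                             lexicon_map = lexicon_map,
                             synonym_prob = config$synonym_prob,
                             typo_rate = config$typo_rate)
      text <- render_document(templates[i], unname(mentions),
                              unname(neg_mentions), med_rows)
    } else {
      text <- render_no_passage_document(med_rows)
    }
    docs[[i]] <- discharge_summary(ids[i], text, gender[i], age[i], year[i],
                                   diabetes[i], pci[i])
    truth_sym[[i]] <- syms
    truth_neg[[i]] <- negs
    truth_med[[i]] <- classes
  }
  truth <- data.frame(doc_id = ids, gender = gender, age_years = age,
                      admission_year = year, diabetes = diabetes, pci = pci,
                      has_passage = has_passage, stringsAsFactors = FALSE)
  truth$true_symptoms <- truth_sym
  truth$negated_mentions <- truth_neg
  truth$true_classes <- truth_med
  list(docs = docs, truth = truth)
}

#' Write ground truth as JSON-lines
#'
#' @param truth Ground-truth data.frame from \code{\link{generate_corpus}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(truth, path) {
  lines <- vapply(seq_len(nrow(truth)), function(i) {
    jsonlite::toJSON(list(
      doc_id = truth$doc_id[i], gender = truth$gender[i],
      age_years = truth$age_years[i],
      admission_year = truth$admission_year[i],
      diabetes = truth$diabetes[i], pci = truth$pci[i],
      has_passage = truth$has_passage[i],
      true_symptoms = truth$true_symptoms[[i]],
      negated_mentions = truth$negated_mentions[[i]],
      true_classes = truth$true_classes[[i]]
    ), auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a ground-truth JSON-lines file
#'
#' @param path Path written by \code{\link{write_truth}}.
#' @return Ground-truth data.frame with list columns.
#' @export
read_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  objs <- lapply(lines, jsonlite::fromJSON)
  chr <- function(f) vapply(objs, function(o) as.character(o[[f]]), "")
  num <- function(f) vapply(objs, function(o) as.numeric(o[[f]]), 0)
  lgl <- function(f) vapply(objs, function(o) isTRUE(o[[f]]), FALSE)
  lst <- function(f) lapply(objs, function(o) as.character(unlist(o[[f]])))
  truth <- data.frame(doc_id = chr("doc_id"), gender = chr("gender"),
                      age_years = num("age_years"),
                      admission_year = num("admission_year"),
                      diabetes = lgl("diabetes"), pci = lgl("pci"),
                      has_passage = lgl("has_passage"),
                      stringsAsFactors = FALSE)
  truth$true_symptoms <- lst("true_symptoms")
  truth$negated_mentions <- lst("negated_mentions")
  truth$true_classes <- lst("true_classes")
  truth
}

#' Score extraction output against ground truth
#'
#' Per-concept and micro-averaged precision, recall and F1 of the predicted
#' symptom (or drug-class) sets against the true sets. A metric with an
#' empty denominator is reported as 1 (vacuously correct).
#'
#' @param truth Ground-truth data.frame from \code{\link{generate_corpus}}.
#' @param results List of \code{cardext_extraction} (or \code{cardext_meds})
#'   objects covering exactly the same doc_ids.
#' @param what \code{"symptoms"} or \code{"medications"}.
#' @return List with \code{per_concept} (data.frame: concept, tp, fp, fn,
#'   precision, recall, f1) and \code{micro} (named list).
#' @export
evaluate_extraction <- function(truth, results,
                                what = c("symptoms", "medications")) {
  what <- match.arg(what)
  pred_ids <- vapply(results, `[[`, "", "doc_id")
  if (!setequal(pred_ids, truth$doc_id) ||
      length(pred_ids) != nrow(truth))
    stop("ground truth and extraction results must cover the same doc_ids",
         call. = FALSE)
  ord <- match(truth$doc_id, pred_ids)
  truth_sets <- if (what == "symptoms") truth$true_symptoms
                else truth$true_classes
  pred_field <- if (what == "symptoms") "symptoms_present" else "classified"
  pred_sets <- lapply(results[ord], `[[`, pred_field)
  concepts <- sort(unique(c(unlist(truth_sets), unlist(pred_sets))))
  tp <- fp <- fn <- stats::setNames(integer(length(concepts)), concepts)
  for (i in seq_along(truth_sets)) {
    t_i <- truth_sets[[i]]; p_i <- pred_sets[[i]]
    hit <- intersect(t_i, p_i)
    tp[hit] <- tp[hit] + 1L
    fp[setdiff(p_i, t_i)] <- fp[setdiff(p_i, t_i)] + 1L
    fn[setdiff(t_i, p_i)] <- fn[setdiff(t_i, p_i)] + 1L
  }
  safe_div <- function(num, den) ifelse(den == 0, 1, num / den)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  micro_p <- safe_div(sum(tp), sum(tp) + sum(fp))
  micro_r <- safe_div(sum(tp), sum(tp) + sum(fn))
  list(
    per_concept = data.frame(concept = concepts, tp = as.integer(tp),
                             fp = as.integer(fp), fn = as.integer(fn),
                             precision = prec, recall = rec, f1 = f1,
                             row.names = NULL, stringsAsFactors = FALSE),
    micro = list(precision = micro_p, recall = micro_r,
                 f1 = if (micro_p + micro_r == 0) 0
                      else 2 * micro_p * micro_r / (micro_p + micro_r))
  )
}
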