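# Cohort assembly and gender-disparity statistics: 2x2 tables, Pearson
# chi-square, Mann-Whitney, univariate odds ratios with Woolf CIs, and
# covariate-adjusted odds ratios from logistic regression.

#' Build the patient-level cohort matrix
#'
#' Joins admission metadata with the symptom and medication extraction
#' outputs, keyed by \code{doc_id}, and computes the document-flow counts
#' (total; with/without detected symptoms; with/without detected
#' medications). Symptom and medication indicators are \code{NA} for
#' documents where the respective extraction found no content.
#'
#' @param docs List of \code{cardext_summary} objects (the metadata source).
#' @param symptom_results List of \code{cardext_extraction} objects.
#' @param medication_results List of \code{cardext_meds} objects (optional).
#' @param lexicon Lexicon defining the symptom indicator columns.
#' @param age_cutoff Age-group cutoff in years (\code{under_45} iff
#'   \code{age_years < age_cutoff}).
#' @return List with \code{cohort} (data.frame, one row per document) and
#'   \code{flow} (named list of counts).
#' @export
build_cohort <- function(docs, symptom_results, medication_results = NULL,
                         lexicon = load_symptom_lexicon(), age_cutoff = 45) {
  meta_ids <- vapply(docs, `[[`, "", "doc_id")
  check_ids <- function(res, what) {
    ids <- vapply(res, `[[`, "", "doc_id")
    missing <- setdiff(ids, meta_ids)
    if (length(missing))
      stop(what, " results reference doc_id(s) absent from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
    ids
  }
  sym_ids <- check_ids(symptom_results, "symptom")
  cohort <- data.frame(
    doc_id = meta_ids,
    gender = vapply(docs, `[[`, "", "gender"),
    age_years = vapply(docs, `[[`, 0, "age_years"),
    admission_year = vapply(docs, function(d) as.numeric(d$admission_year), 0),
    diabetes = vapply(docs, `[[`, FALSE, "diabetes"),
    pci = vapply(docs, `[[`, FALSE, "pci"),
    stringsAsFactors = FALSE
  )
  cohort$age_group <- factor(
    ifelse(cohort$age_years < age_cutoff, "under_45", "over_45"),
    levels = c("over_45", "under_45")
  )
  smat <- symptom_matrix(symptom_results, lexicon)
  sym_cols <- attr(smat, "symptom_names")
  m <- match(cohort$doc_id, smat$doc_id)
  cohort$passage_found <- ifelse(is.na(m), FALSE, smat$passage_found[m])
  cohort$symptoms_detected <- rep(FALSE, nrow(cohort))
  ok <- !is.na(m)
  cohort$symptoms_detected[ok] <- vapply(
    symptom_results[m[ok]], function(r) length(r$symptoms_present) > 0L, FALSE)
  for (col in sym_cols) {
    v <- rep(NA, nrow(cohort))
    v[ok] <- smat[[col]][m[ok]]
    v[!cohort$passage_found] <- NA
    cohort[[col]] <- v
  }
  cohort$meds_found <- rep(FALSE, nrow(cohort))
  med_cols <- character(0)
  if (!is.null(medication_results)) {
    check_ids(medication_results, "medication")
    mmat <- medication_matrix(medication_results)
    med_cols <- attr(mmat, "class_names")
    mm <- match(cohort$doc_id, mmat$doc_id)
    okm <- !is.na(mm)
    cohort$meds_found[okm] <- mmat$meds_found[mm[okm]]
    for (col in med_cols) {
      v <- rep(NA, nrow(cohort))
      v[okm] <- mmat[[col]][mm[okm]]
      v[!cohort$meds_found] <- NA
      cohort[[col]] <- v
    }
  }
  attr(cohort, "symptom_names") <- sym_cols
  attr(cohort, "class_names") <- med_cols
  flow <- list(
    total = nrow(cohort),
    with_symptoms = sum(cohort$symptoms_detected),
    without_symptoms = sum(!cohort$symptoms_detected),
    with_meds = sum(cohort$meds_found),
    without_meds = sum(!cohort$meds_found)
  )
  list(cohort = cohort, flow = flow)
}

resolve_outcome_col <- function(cohort, outcome) {
  sym_cols <- attr(cohort, "symptom_names")
  med_cols <- attr(cohort, "class_names")
  if (outcome %in% names(sym_cols))
    return(list(col = sym_cols[[outcome]], kind = "symptom"))
  if (outcome %in% names(med_cols))
    return(list(col = med_cols[[outcome]], kind = "medication"))
  if (outcome %in% names(cohort))
    return(list(col = outcome,
                kind = if (startsWith(outcome, "med_")) "medication" else "symptom"))
  stop("unknown outcome '", outcome, "'", call. = FALSE)
}

#' Construct a 2x2 gender-by-outcome contingency table
#'
#' Exposure is gender (women exposed); \code{a} = women with outcome,
#' \code{b} = women without, \code{c} = men with, \code{d} = men without.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A \code{cardext_table2x2}.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "cardext_table2x2")
}

#' Tabulate an outcome against gender in a cohort
#'
#' Denominators are restricted to the records where the relevant extraction
#' found content: for symptom outcomes the records with a located
#' presenting-complaint passage (when \code{symptomatic_only}); for
#' medication outcomes the records with a detected medication table.
#'
#' @param cohort Cohort data.frame from \code{\link{build_cohort}}.
#' @param outcome Canonical symptom name, drug class, or indicator column.
#' @param symptomatic_only Restrict symptom denominators to passage-found
#'   records (default TRUE).
#' @return A \code{cardext_table2x2}.
#' @export
contingency <- function(cohort, outcome, symptomatic_only = TRUE) {
  if (is.list(cohort) && !is.data.frame(cohort) && !is.null(cohort$cohort))
    cohort <- cohort$cohort
  res <- resolve_outcome_col(cohort, outcome)
  keep <- if (res$kind == "medication") cohort$meds_found
          else if (symptomatic_only) cohort$passage_found
          else rep(TRUE, nrow(cohort))
  sub <- cohort[keep & !is.na(cohort[[res$col]]), , drop = FALSE]
  w <- sub$gender == "woman"
  y <- as.logical(sub[[res$col]])
  contingency_table(sum(w & y), sum(w & !y), sum(!w & y), sum(!w & !y))
}

or_result <- function(or_point = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      method, omitted = FALSE, reason = NA_character_) {
  structure(list(or_point = or_point, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, method = method, omitted = omitted,
                 reason = reason),
            class = "cardext_or")
}

#' @export
print.cardext_or <- function(x, digits = 3, ...) {
  if (x$omitted) {
    cat("OR omitted (", x$reason, ") [", x$method, "]\n", sep = "")
  } else {
    cat(sprintf("OR %.*f (95%% CI %.*f-%.*f), p = %.3g [%s]\n",
                digits, x$or_point, digits, x$ci_low, digits, x$ci_high,
                x$p_value, x$method))
  }
  invisible(x)
}

#' Univariate odds ratio with Woolf confidence interval
#'
#' \code{OR = (a d)/(b c)} with the Woolf (log-normal) interval
#' \code{exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))}. Any zero cell
#' yields \code{omitted = TRUE} (no continuity correction), matching the
#' convention of omitting inestimable rows rather than correcting them. The
#' p-value is the Wald test on the log odds ratio.
#'
#' @param table A \code{cardext_table2x2}.
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return A \code{cardext_or} with method \code{"univariate_woolf"}.
#' @export
odds_ratio_univariate <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "cardext_table2x2"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (min(a, b, cc, d) == 0L)
    return(or_result(method = "univariate_woolf", omitted = TRUE,
                     reason = "zero cell"))
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  or_result(or, exp(log(or) - z * se), exp(log(or) + z * se), p,
            method = "univariate_woolf")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction), 1 degree of freedom. A zero
#' row or column margin makes the statistic undefined: both values are
#' returned as \code{NA} with a warning.
#'
#' @param table A \code{cardext_table2x2}.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
chi_square <- function(table) {
  stopifnot(inherits(table, "cardext_table2x2"))
  O <- matrix(c(table$a, table$b, table$c, table$d), nrow = 2, byrow = TRUE)
  rs <- rowSums(O); cs <- colSums(O); n <- sum(O)
  if (any(rs == 0) || any(cs == 0)) {
    warning("zero margin: chi-square statistic undefined")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  E <- outer(rs, cs) / n
  stat <- sum((O - E)^2 / E)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided. Uses the exact null distribution when both groups have at most
#' 20 observations and there are no ties; otherwise the tie-corrected normal
#' approximation. The reported U statistic is for the first group.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param exact_max Per-group size limit for the exact distribution.
#' @return List with \code{U} and \code{p_value}.
#' @export
mann_whitney <- function(values_a, values_b, exact_max = 20L) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(values_a); n2 <- length(values_b)
  combined <- c(values_a, values_b)
  r <- rank(combined)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(combined))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    return(list(U = U, p_value = min(1, p)))
  }
  N <- n1 + n2
  tie_tab <- table(combined)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1))
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  list(U = U, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Covariate-adjusted odds ratio for gender from logistic regression
#'
#' Fits \code{outcome ~ gender + covariates} by maximum likelihood (IRLS,
#' convergence tolerance 1e-12, at most 100 iterations) on the records where
#' the relevant extraction found content, and returns the exponentiated
#' gender (woman vs man) coefficient with its Wald 95% CI. Constant
#' covariates are dropped (with a message), so with all covariates constant
#' the estimate reduces to the univariate odds ratio. Non-convergence or
#' (quasi-)separation yields \code{omitted = TRUE}.
#'
#' @param cohort Cohort data.frame from \code{\link{build_cohort}}.
#' @param outcome Canonical symptom name or drug class.
#' @param covariates Covariate column names; \code{diabetes}/\code{pci} are
#'   binary, \code{age_group} binary (under vs over 45), \code{age_years}
#'   continuous, \code{admission_year} centered continuous.
#' @param alpha Two-sided significance level.
#' @param symptomatic_only Restrict symptom outcomes to passage-found records.
#' @return A \code{cardext_or} with method \code{"logistic_adjusted"}.
#' @export
odds_ratio_adjusted <- function(cohort, outcome,
                                covariates = c("diabetes", "age_group"),
                                alpha = 0.05, symptomatic_only = TRUE) {
  if (is.list(cohort) && !is.data.frame(cohort) && !is.null(cohort$cohort))
    cohort <- cohort$cohort
  res <- resolve_outcome_col(cohort, outcome)
  keep <- if (res$kind == "medication") cohort$meds_found
          else if (symptomatic_only) cohort$passage_found
          else rep(TRUE, nrow(cohort))
  sub <- cohort[keep & !is.na(cohort[[res$col]]), , drop = FALSE]
  if (!nrow(sub))
    return(or_result(method = "logistic_adjusted", omitted = TRUE,
                     reason = "no eligible records"))
  y <- as.logical(sub[[res$col]])
  if (length(unique(y)) < 2L)
    return(or_result(method = "logistic_adjusted", omitted = TRUE,
                     reason = "degenerate outcome"))
  df <- data.frame(.y = y,
                   gender = factor(sub$gender, levels = c("man", "woman")))
  kept <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(sub)) stop("unknown covariate '", cv, "'", call. = FALSE)
    v <- sub[[cv]]
    if (identical(cv, "admission_year")) v <- v - mean(v)
    if (length(unique(stats::na.omit(v))) < 2L) {
      message("dropping constant covariate '", cv, "'")
      next
    }
    df[[cv]] <- v
    kept <- c(kept, cv)
  }
  form <- stats::as.formula(paste(".y ~ gender",
                                  if (length(kept))
                                    paste("+", paste(kept, collapse = " + "))
                                  else ""))
  fit <- tryCatch(
    stats::glm(form, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    error = function(e) e, warning = function(w) w
  )
  if (inherits(fit, "condition")) {
    if (inherits(fit, "warning"))
      fit <- suppressWarnings(
        stats::glm(form, data = df, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
    else
      return(or_result(method = "logistic_adjusted", omitted = TRUE,
                       reason = paste("fit failed:", conditionMessage(fit))))
  }
  if (!fit$converged)
    return(or_result(method = "logistic_adjusted", omitted = TRUE,
                     reason = "did not converge"))
  co <- summary(fit)$coefficients
  if (!"genderwoman" %in% rownames(co))
    return(or_result(method = "logistic_adjusted", omitted = TRUE,
                     reason = "gender coefficient not estimable"))
  est <- co["genderwoman", "Estimate"]
  se <- co["genderwoman", "Std. Error"]
  if (!is.finite(est) || !is.finite(se) || abs(est) > 15 || se > 100)
    return(or_result(method = "logistic_adjusted", omitted = TRUE,
                     reason = "separation"))
  z <- stats::qnorm(1 - alpha / 2)
  or_result(exp(est), exp(est - z * se), exp(est + z * se),
            2 * stats::pnorm(-abs(est / se)),
            method = "logistic_adjusted")
}

# ---- table rendering --------------------------------------------------------

fmt_pct <- function(x, digits) formatC(100 * x, format = "f", digits = digits)

#' Render the three disparity tables
#'
#' Produces (1) a symptom frequency table with per-gender counts, percentages
#' (two decimals) and chi-square p-values; (2) a symptom odds-ratio table with
#' univariate (Woolf) and multivariable (adjusted) estimates; (3) the same
#' pair for medication classes. Rows are ordered by descending total
#' frequency; inestimable odds ratios are marked "Omitted".
#'
#' @param cohort Output of \code{\link{build_cohort}} (or its \code{cohort}
#'   data.frame).
#' @param symptom_covariates,medication_covariates Adjustment sets for the
#'   multivariable models.
#' @return List of data.frames: \code{symptoms}, \code{symptom_or},
#'   \code{medications}.
#' @export
render_tables <- function(cohort,
                          symptom_covariates = c("diabetes", "age_group"),
                          medication_covariates = c("diabetes", "pci",
                                                    "admission_year")) {
  if (is.list(cohort) && !is.data.frame(cohort) && !is.null(cohort$cohort))
    cohort <- cohort$cohort
  sym_cols <- attr(cohort, "symptom_names")
  med_cols <- attr(cohort, "class_names")

  freq_block <- function(outcomes) {
    rows <- lapply(outcomes, function(oc) {
      tb <- contingency(cohort, oc)
      n_w <- tb$a + tb$b; n_m <- tb$c + tb$d
      total <- tb$a + tb$c; n <- n_w + n_m
      cs <- suppressWarnings(chi_square(tb))
      data.frame(
        outcome = oc, total_n = total,
        total_pct = if (n) fmt_pct(total / n, 2) else NA,
        women_n = tb$a, women_pct = if (n_w) fmt_pct(tb$a / n_w, 2) else NA,
        men_n = tb$c, men_pct = if (n_m) fmt_pct(tb$c / n_m, 2) else NA,
        p_value = cs$p_value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(-out$total_n), , drop = FALSE]
  }
  or_block <- function(outcomes, covariates) {
    rows <- lapply(outcomes, function(oc) {
      tb <- contingency(cohort, oc)
      uni <- odds_ratio_univariate(tb)
      adj <- odds_ratio_adjusted(cohort, oc, covariates)
      n <- tb$a + tb$b + tb$c + tb$d
      total <- tb$a + tb$c
      fmt_or <- function(r)
        if (r$omitted) "Omitted"
        else sprintf("%.2f (%.2f-%.2f)", r$or_point, r$ci_low, r$ci_high)
      data.frame(
        outcome = oc, total_n = total,
        total_pct = if (n) fmt_pct(total / n, 1) else NA,
        univariate_or = fmt_or(uni), univariate_p = uni$p_value,
        adjusted_or = fmt_or(adj), adjusted_p = adj$p_value,
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(-out$total_n), , drop = FALSE]
  }
  symptoms <- if (nrow(cohort)) names(sym_cols) else character(0)
  meds <- if (nrow(cohort)) names(med_cols) else character(0)
  list(
    symptoms = if (length(symptoms)) freq_block(symptoms) else
      data.frame(outcome = character(0)),
    symptom_or = if (length(symptoms)) or_block(symptoms, symptom_covariates)
      else data.frame(outcome = character(0)),
    medications = if (length(meds)) or_block(meds, medication_covariates)
      else data.frame(outcome = character(0))
  )
}
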