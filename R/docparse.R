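# Section segmentation and table detection for discharge-summary text.
# All coordinates are 0-based, half-open character offsets into the document.

#' Construct a discharge summary
#'
#' Bundles the free text of one discharge summary with the structured
#' admission metadata used by the disparity analysis.
#'
#' @param doc_id Unique document identifier.
#' @param text Full document text.
#' @param gender \code{"woman"} or \code{"man"}.
#' @param age_years Age at admission in years (>= 0).
#' @param admission_year Calendar year of admission.
#' @param diabetes,pci Logical comorbidity / procedure flags.
#' @param year_range Permitted admission-year range (dataset coverage).
#' @return A \code{cardext_summary} object.
#' @export
discharge_summary <- function(doc_id, text, gender, age_years, admission_year,
                              diabetes = FALSE, pci = FALSE,
                              year_range = c(1988L, 2018L)) {
  gender <- match.arg(gender, c("woman", "man"))
  age_years <- as.numeric(age_years)
  admission_year <- as.integer(admission_year)
  if (is.na(age_years) || age_years < 0)
    stop("age_years must be a non-negative number", call. = FALSE)
  if (is.na(admission_year) || admission_year < year_range[1] ||
      admission_year > year_range[2])
    stop("admission_year ", admission_year, " outside permitted range ",
         year_range[1], "-", year_range[2], call. = FALSE)
  structure(
    list(doc_id = as.character(doc_id), text = as.character(text),
         gender = gender, age_years = age_years,
         admission_year = admission_year, diabetes = isTRUE(diabetes),
         pci = isTRUE(pci)),
    class = "cardext_summary"
  )
}

new_passage <- function(text, section_label, start_offset, end_offset) {
  stopifnot(start_offset >= 0, start_offset < end_offset)
  structure(list(text = text, section_label = section_label,
                 start_offset = as.integer(start_offset),
                 end_offset = as.integer(end_offset)),
            class = "cardext_passage")
}

#' Default section-heading patterns
#'
#' Regular expressions (matched case-insensitively at line starts, followed by
#' an optional-colon terminator) that open a new section. Override to adapt to
#' a site's templates.
#' @return Character vector of regex strings.
#' @export
heading_patterns <- function() c(
  "presenting complaints?",
  "chief complaints?",
  "presenting symptoms?",
  "history of present(?:ing)? illness",
  "hospital course",
  "physical examination",
  "examination",
  "investigations?",
  "assessment",
  "plan",
  "procedures?",
  "discharge medications?",
  "medications? on discharge",
  "follow ?up"
)

#' Default presenting-complaint heading patterns
#' @return Character vector of regex strings matched against section labels.
#' @export
presenting_heading_patterns <- function() c(
  "presenting complaints?",
  "chief complaints?",
  "presenting symptoms?",
  "history of present(?:ing)? illness"
)

#' Default trigger phrases for presenting-complaint fallback detection
#' @return Character vector of normalized phrases.
#' @export
trigger_phrases <- function() c(
  "presented with", "presents with", "complaints of", "complained of",
  "complaining of"
)

#' Default medication-table indicator terms
#' @return Character vector of normalized phrases.
#' @export
medication_indicator_terms <- function() c(
  "discharge medications", "medications on discharge", "discharge medication"
)

compile_heading_regex <- function(patterns) {
  if (!length(patterns)) return(NULL)
  rx <- paste0("^[[:blank:]]*(?:", paste(patterns, collapse = "|"),
               ")[[:blank:]]*:")
  ok <- tryCatch({
    suppressWarnings(grepl(rx, "probe", perl = TRUE, ignore.case = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("invalid heading regex in configuration", call. = FALSE)
  rx
}

# Line starts (0-based offsets) and line text, without consuming separators.
split_lines_keep <- function(text) {
  nlpos <- gregexpr("\n", text, fixed = TRUE)[[1]]
  starts <- if (nlpos[1] == -1L) 0L else c(0L, as.integer(nlpos))
  ends <- c(starts[-1] - 1L, nchar(text))  # 0-based, exclusive of "\n"
  list(start = starts, end = ends,
       line = substring(text, starts + 1L, ends))
}

#' Segment a document into labeled sections
#'
#' Splits the document at lines matching any heading pattern. Passages are
#' non-overlapping, ordered and cover the document exactly: concatenating
#' their texts reconstructs the input. Text before the first heading is
#' labeled \code{"preamble"}.
#'
#' @param text Document string.
#' @param patterns Heading regexes, see \code{\link{heading_patterns}}.
#' @return List of \code{cardext_passage} objects.
#' @export
segment_sections <- function(text, patterns = heading_patterns()) {
  stopifnot(is.character(text), length(text) == 1L)
  rx <- compile_heading_regex(patterns)
  n <- nchar(text)
  if (n == 0L) return(list())
  li <- split_lines_keep(text)
  is_head <- if (is.null(rx)) rep(FALSE, length(li$line))
             else grepl(rx, li$line, perl = TRUE, ignore.case = TRUE)
  head_idx <- which(is_head)
  passages <- list()
  if (!length(head_idx)) {
    return(list(new_passage(text, "preamble", 0L, n)))
  }
  first_head_start <- li$start[head_idx[1]]
  if (first_head_start > 0L)
    passages[[length(passages) + 1L]] <-
      new_passage(substring(text, 1L, first_head_start), "preamble",
                  0L, first_head_start)
  bounds <- c(li$start[head_idx], n)
  for (i in seq_along(head_idx)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    label <- sub(":.*$", "", li$line[head_idx[i]])
    passages[[length(passages) + 1L]] <-
      new_passage(substring(text, s + 1L, e), normalize_term(label), s, e)
  }
  passages
}

#' Locate the presenting-complaint passage
#'
#' Returns the first section whose heading matches a presenting-complaint
#' pattern; failing that, the earliest section whose text contains a trigger
#' phrase (e.g. "presented with"); failing that, \code{NULL}. An absent
#' passage is a valid outcome, used by the pipeline's flow accounting for
#' documents with no detected symptoms.
#'
#' @param doc A \code{cardext_summary} (or a raw document string).
#' @param patterns Section-heading regexes.
#' @param presenting Presenting-heading regexes.
#' @param triggers Trigger phrases (compared on normalized text).
#' @return A \code{cardext_passage} or \code{NULL}.
#' @export
extract_presenting_passage <- function(doc,
                                       patterns = heading_patterns(),
                                       presenting = presenting_heading_patterns(),
                                       triggers = trigger_phrases()) {
  text <- if (inherits(doc, "cardext_summary")) doc$text else doc
  if (!nzchar(text)) return(NULL)
  li <- split_lines_keep(text)
  rx <- compile_heading_regex(patterns)
  is_head <- if (is.null(rx)) rep(FALSE, length(li$line))
             else grepl(rx, li$line, perl = TRUE, ignore.case = TRUE)
  head_starts <- li$start[is_head]
  n <- nchar(text)
  slice <- function(s) {
    nxt <- head_starts[head_starts > s]
    e <- if (length(nxt)) nxt[1] else n
    label <- if (s %in% head_starts)
      normalize_term(sub(":.*$", "", li$line[match(s, li$start)]))
    else "preamble"
    new_passage(substring(text, s + 1L, e), label, s, e)
  }
  pres_rx <- compile_heading_regex(presenting)
  pres_hit <- which(is_head &
                      grepl(pres_rx, li$line, perl = TRUE, ignore.case = TRUE))
  if (length(pres_hit)) return(slice(li$start[pres_hit[1]]))
  # fallback: earliest trigger-phrase occurrence, word gaps tolerant of
  # punctuation the way normalize_term is
  trx <- paste0("(?:", paste(gsub(" ", "[^a-z0-9]+",
                                  normalize_term(triggers), fixed = TRUE),
                             collapse = "|"), ")")
  m <- regexpr(trx, tolower(text), perl = TRUE)
  if (m == -1L) return(NULL)
  pos0 <- as.integer(m) - 1L
  cand <- c(0L, head_starts)
  slice(max(cand[cand <= pos0]))
}

#' Detect discharge-medication table regions
#'
#' Scans for lines whose normalized content starts with an indicator term
#' (e.g. "discharge medications"). Each region extends from the line after
#' the indicator to the next section heading or end of document and is split
#' into non-empty row strings, in source order.
#'
#' @param text Document string.
#' @param indicators Indicator phrases (normalized comparison).
#' @param patterns Heading regexes delimiting the region's end.
#' @return List of regions, each with \code{rows}, \code{start_offset},
#'   \code{end_offset}, \code{indicator_term}.
#' @export
detect_medication_tables <- function(text,
                                     indicators = medication_indicator_terms(),
                                     patterns = heading_patterns()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(list())
  indicators <- normalize_term(indicators)
  li <- split_lines_keep(text)
  norm_lines <- normalize_term(li$line)
  is_ind <- vapply(norm_lines, function(ln) {
    nzchar(ln) && any(startsWith(ln, indicators))
  }, FALSE, USE.NAMES = FALSE)
  rx <- compile_heading_regex(patterns)
  is_head <- if (is.null(rx)) rep(FALSE, length(li$line))
             else grepl(rx, li$line, perl = TRUE, ignore.case = TRUE)
  regions <- list()
  for (i in which(is_ind)) {
    if (i == length(li$line)) next               # indicator on last line
    first <- i + 1L
    nxt <- which(is_head & seq_along(is_head) >= first)
    last <- if (length(nxt)) nxt[1] - 1L else length(li$line)
    if (last < first) next
    rows <- trimws(li$line[first:last])
    rows <- rows[nzchar(rows)]
    if (!length(rows)) next
    regions[[length(regions) + 1L]] <- list(
      rows = rows,
      start_offset = li$start[first],
      end_offset = li$end[last],
      indicator_term = trimws(li$line[i])
    )
  }
  regions
}

# ---- corpus I/O -------------------------------------------------------------

#' Read a JSON-lines corpus of discharge summaries
#'
#' Each line is one JSON object with fields \code{doc_id}, \code{text},
#' \code{gender}, \code{age_years}, \code{admission_year}, \code{diabetes},
#' \code{pci}.
#'
#' @param path Path to a .jsonl file.
#' @param year_range Permitted admission-year range.
#' @return List of \code{cardext_summary} objects.
#' @export
read_corpus <- function(path, year_range = c(1988L, 2018L)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop("malformed JSON on line ", i, " of ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    discharge_summary(obj$doc_id, obj$text, obj$gender, obj$age_years,
                      obj$admission_year, isTRUE(obj$diabetes),
                      isTRUE(obj$pci), year_range = year_range)
  })
  ids <- vapply(docs, `[[`, "", "doc_id")
  if (anyDuplicated(ids))
    stop("duplicate doc_id(s) in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  docs
}

#' Write discharge summaries as a JSON-lines corpus
#'
#' @param docs List of \code{cardext_summary} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_corpus <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(
      list(doc_id = d$doc_id, text = d$text, gender = d$gender,
           age_years = d$age_years, admission_year = d$admission_year,
           diabetes = d$diabetes, pci = d$pci),
      auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
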