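#' Strip markup remnants from report text
#'
#' Laboratory exports carry HTML artifacts (`<br>`, `&nbsp;`, stray angle
#' brackets). These are replaced by single spaces and runs of whitespace are
#' collapsed, so keyword positions are stable on the cleaned text. All section
#' spans and character indices produced by this package refer to the cleaned
#' text.
#'
#' @param text Character vector.
#' @return Cleaned character vector.
#' @export
normalize_markup <- function(text) {
  x <- stringi::stri_replace_all_regex(
    text, "(?i)<br\\s*/?>|&nbsp;|&amp;|&lt;|&gt;|</?[a-z][a-z0-9]*[^<>]*>", " ")
  x <- stringi::stri_replace_all_regex(x, "[<>]", " ")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  trimws(x)
}

# first case-insensitive occurrence of any phrase; list(start, end) or NULL
.locate_first <- function(text, phrases) {
  loc <- stringi::stri_locate_first_fixed(
    text, phrases,
    opts_fixed = stringi::stri_opts_fixed(case_insensitive = TRUE))
  starts <- loc[, 1]
  if (all(is.na(starts))) return(NULL)
  i <- which.min(starts)
  list(start = unname(loc[i, 1]), end = unname(loc[i, 2]))
}

#' Locate a section keyword
#'
#' Returns the smallest 1-based character position at which any of the given
#' phrases occurs in `text`, case-insensitively (first-position semantics, no
#' word-boundary anchoring, mirroring a spreadsheet-style SEARCH).
#'
#' @param text A single string.
#' @param phrases Non-empty character vector of keyword phrases.
#' @return Integer position, or `NA` if no phrase occurs.
#' @export
locate_keyword <- function(text, phrases) {
  stopifnot(length(phrases) >= 1)
  if (length(text) != 1 || is.na(text)) return(NA_integer_)
  hit <- .locate_first(text, phrases)
  if (is.null(hit)) NA_integer_ else as.integer(hit$start)
}

# Full section geometry on cleaned text. Intervals are 1-based half-open
# [start, end); a missing section yields NULL components.
.section_spans <- function(text, keywords) {
  stopifnot(inherits(keywords, "ptr_keywords"))
  n <- nchar(text)
  d  <- .locate_first(text, keywords$diagnosis_start)
  p  <- .locate_first(text, keywords$prognosis)
  ch <- .locate_first(text, keywords$clinical_history)
  h  <- .locate_first(text, keywords$histology)
  cm <- .locate_first(text, keywords$comments)
  span <- function(from, stops) {
    # from = first char after the opening keyword; stops = candidate
    # terminator start positions (NA dropped); absent terminator -> end of text
    stops <- stops[!is.na(stops)]
    to <- if (length(stops)) min(stops) else n + 1L
    if (is.null(from) || to <= from) return(NULL)
    c(start = from, end = to)
  }
  diagnosis <- if (!is.null(d)) {
    span(d$end + 1L, c(if (!is.null(p)) p$start, if (!is.null(ch)) ch$start))
  }
  clin_hist <- if (!is.null(ch)) {
    span(ch$end + 1L, c(if (!is.null(h)) h$start))
  }
  histo <- if (!is.null(h)) {
    span(h$end + 1L, c(if (!is.null(cm)) cm$start))
  }
  cut <- function(iv) {
    if (is.null(iv)) "" else trimws(substr(text, iv["start"], iv["end"] - 1L))
  }
  list(
    positions = list(
      diagnosis = if (is.null(d)) NA_integer_ else as.integer(d$start),
      prognosis = if (is.null(p)) NA_integer_ else as.integer(p$start),
      clinical_history = if (is.null(ch)) NA_integer_ else as.integer(ch$start),
      histology = if (is.null(h)) NA_integer_ else as.integer(h$start),
      comments = if (is.null(cm)) NA_integer_ else as.integer(cm$start)
    ),
    diagnosis_interval = diagnosis,
    diagnosis_text = cut(diagnosis),
    clinical_history_text = cut(clin_hist),
    histology_text = cut(histo)
  )
}

.record_text <- function(record) {
  if (is.character(record)) return(record[[1]])
  record$report_text[[1]]
}

#' Extract the diagnosis section of a report
#'
#' The diagnosis span runs from the end of the diagnosis-start keyword
#' (DIAGNOSIS, or CYTOLOGICAL INTERPRETATION on cytology reports) to the
#' first of the PROGNOSIS or CLINICAL HISTORY keywords; when neither
#' terminator is present the span runs to the end of the text, and when the
#' diagnosis keyword itself is absent the span is empty. Markup is stripped
#' with [normalize_markup()] first.
#'
#' @param record An EPR record (one-row `ptr_epr` data frame, a list with a
#'   `report_text` element, or a plain string).
#' @param keywords A `ptr_keywords` object from [dialect_keywords()].
#' @return The diagnosis section text (possibly `""`), trimmed.
#' @export
extract_diagnosis_section <- function(record, keywords) {
  text <- normalize_markup(.record_text(record))
  .section_spans(text, keywords)$diagnosis_text
}

#' Ranked lesion-location source spans
#'
#' Location phrases can sit in one of three report regions, consulted in
#' priority order: rank 1 is the diagnosis-adjacent text, rank 2 the span
#' between CLINICAL HISTORY and HISTOLOGY, rank 3 the span between HISTOLOGY
#' and COMMENTS. Missing sections yield missing candidates; ranks are
#' preserved.
#'
#' @inheritParams extract_diagnosis_section
#' @return A data frame with columns `rank` (integer) and `text`, at most
#'   three rows.
#' @export
extract_location_candidates <- function(record, keywords) {
  text <- normalize_markup(.record_text(record))
  sp <- .section_spans(text, keywords)
  cand <- data.frame(
    rank = 1:3,
    text = c(sp$diagnosis_text, sp$clinical_history_text, sp$histology_text),
    stringsAsFactors = FALSE
  )
  cand[nzchar(cand$text), , drop = FALSE]
}
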