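# Lesion separation: a diagnosis span holds 1..6 lesions, delimited by
# "1."-"6." or by standalone letters A-F. Only these markers are searched,
# which caps the lesion count at six by construction; text after a seventh
# item stays attached to lesion six.

# first occurrence of each numeric marker "1."-"6.", sorted by position
.numeric_markers <- function(x) {
  pats <- paste0(1:6, ".")
  loc <- stringi::stri_locate_first_fixed(x, pats)
  keep <- !is.na(loc[, 1])
  m <- data.frame(start = loc[keep, 1], end = loc[keep, 2])
  m[order(m$start), , drop = FALSE]
}

# alphabetic markers: standalone tokens A-F (optionally followed by "." or
# ")"), accepted only as an increasing alphabetical chain starting at A
.alpha_markers <- function(x) {
  loc <- stringi::stri_locate_all_regex(
    x, "(?:^|(?<=\\s))[A-F][.)]?(?=\\s|$)")[[1]]
  if (all(is.na(loc[, 1]))) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  letters_found <- substr(rep(x, nrow(loc)), loc[, 1], loc[, 1])
  expected <- "A"
  keep <- logical(nrow(loc))
  for (i in seq_len(nrow(loc))) {
    if (letters_found[i] == expected) {
      keep[i] <- TRUE
      expected <- LETTERS[match(expected, LETTERS) + 1L]
      if (is.na(match(expected, c("A", "B", "C", "D", "E", "F")))) break
    }
  }
  data.frame(start = loc[keep, 1], end = loc[keep, 2])
}

#' Detect the lesion delimiter style of a diagnosis span
#'
#' @param diagnosis_span Diagnosis section text.
#' @return `"numeric"` if "1." occurs and "2." occurs after it, else
#'   `"alphabetic"` if an A/B list-marker pattern is present, else `"none"`.
#' @export
detect_delimiter_style <- function(diagnosis_span) {
  if (length(diagnosis_span) != 1 || is.na(diagnosis_span)) return("none")
  p1 <- stringi::stri_locate_first_fixed(diagnosis_span, "1.")[1, 1]
  p2 <- stringi::stri_locate_first_fixed(diagnosis_span, "2.")[1, 1]
  if (!is.na(p1) && !is.na(p2) && p2 > p1) return("numeric")
  if (nrow(.alpha_markers(diagnosis_span)) >= 2) return("alphabetic")
  "none"
}

#' Split a diagnosis span into individual lesions
#'
#' Numeric delimiters "1."-"6." take precedence; failing those, alphabetic
#' markers A-F are tried; with neither, the whole span is a single lesion.
#' Each lesion is the text between consecutive markers (marker stripped,
#' whitespace trimmed); at most six lesions are returned and material after a
#' hypothetical seventh marker stays attached to lesion six. Out-of-order
#' numeric markers still count as numeric; slicing starts at the earliest
#' marker found.
#'
#' @param diagnosis_span Diagnosis section text.
#' @return A data frame with columns `ordinal` (1..6, contiguous) and `text`;
#'   zero rows for an empty span.
#' @export
split_lesions <- function(diagnosis_span) {
  empty <- data.frame(ordinal = integer(0), text = character(0),
                      stringsAsFactors = FALSE)
  if (length(diagnosis_span) != 1 || is.na(diagnosis_span)) return(empty)
  span <- diagnosis_span
  if (!nzchar(trimws(span))) return(empty)
  m <- .numeric_markers(span)
  if (nrow(m) < 2) m <- .alpha_markers(span)
  if (nrow(m) < 2) {
    texts <- trimws(span)
  } else {
    froms <- m$end + 1L
    tos <- c(m$start[-1] - 1L, nchar(span))
    texts <- trimws(substr(rep(span, nrow(m)), froms, tos))
  }
  texts <- texts[nzchar(texts)]
  if (length(texts) == 0) return(empty)
  data.frame(ordinal = seq_along(texts), text = texts,
             stringsAsFactors = FALSE)
}
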