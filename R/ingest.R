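#' Read a laboratory tabular export
#'
#' Reads a delimited export of pathology submissions (one or more rows per
#' submission) with at least the columns LABNO and RESCOMMENT (a column whose
#' name starts with RESCOMMENT also counts); RECD, SPECIES, BREED, GENDER,
#' PRACTICE_ID and ASSAY_CODE are used when present. Header matching is
#' case-insensitive. Dates are parsed day-first (UK convention); values that
#' fail to parse are kept verbatim in `recd_raw` rather than dropped.
#'
#' @param path Path to a CSV or TSV file (separator auto-detected from the
#'   extension unless `sep` is given).
#' @param dialect Laboratory dialect id carried through to downstream steps.
#' @param sep Field separator; `NULL` for auto-detection.
#' @return A data frame of class `ptr_lab_export` with columns `lab_no`,
#'   `recd` (Date), `recd_raw`, `species`, `breed`, `gender`, `practice_id`,
#'   `assay_code`, `rescomment`, one row per data line in file order.
#' @export
read_lab_export <- function(path, dialect = "lab_a", sep = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop("cannot read lab export, file not found: ", path)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fill = TRUE,
                           comment.char = "", fileEncoding = "UTF-8")
  hdr <- toupper(trimws(names(raw)))
  pick <- function(name, prefix = FALSE, required = FALSE) {
    i <- if (prefix) which(startsWith(hdr, name)) else which(hdr == name)
    if (length(i) == 0) {
      if (required) stop("lab export is missing mandatory column: ", name)
      return(rep("", nrow(raw)))
    }
    as.character(raw[[i[1]]])
  }
  lab_no <- trimws(pick("LABNO", required = TRUE))
  if (nrow(raw) > 0 && any(!nzchar(lab_no))) {
    stop("lab export contains rows with an empty LABNO")
  }
  recd_raw <- pick("RECD")
  out <- data.frame(
    lab_no = lab_no,
    recd = parse_date_dayfirst(recd_raw),
    recd_raw = recd_raw,
    species = pick("SPECIES"),
    breed = pick("BREED"),
    gender = pick("GENDER"),
    practice_id = pick("PRACTICE_ID"),
    assay_code = pick("ASSAY_CODE"),
    rescomment = pick("RESCOMMENT", prefix = TRUE, required = TRUE),
    stringsAsFactors = FALSE
  )
  attr(out, "dialect") <- dialect
  class(out) <- c("ptr_lab_export", "data.frame")
  out
}

#' Parse dates day-first
#'
#' Accepts `dd/mm/yy`, `dd/mm/yyyy`, `dd-mm-yyyy` and ISO `yyyy-mm-dd`.
#' Two-digit years pivot at 2000 (00-68 map to 2000s).
#'
#' @param x Character vector of date strings.
#' @return A `Date` vector; unparseable entries are `NA`.
#' @export
parse_date_dayfirst <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  pats <- list(c("^\\d{4}-\\d{1,2}-\\d{1,2}$", "%Y-%m-%d"),
               c("^\\d{1,2}/\\d{1,2}/\\d{4}$", "%d/%m/%Y"),
               c("^\\d{1,2}/\\d{1,2}/\\d{2}$", "%d/%m/%y"),
               c("^\\d{1,2}-\\d{1,2}-\\d{4}$", "%d-%m-%Y"))
  for (p in pats) {
    sel <- is.na(out) & grepl(p[1], x)
    if (any(sel)) out[sel] <- as.Date(x[sel], format = p[2])
  }
  out
}

#' Concatenate multi-row submissions into one record per submission
#'
#' Laboratories may deliver one submission as a series of consecutive rows
#' sharing the sample reference; their free-text fragments are joined in order
#' with a single newline. Grouping is by runs of consecutive equal `lab_no`:
#' a reference that reappears non-adjacently is treated as a distinct
#' submission and a warning is emitted. Animal metadata is taken from the
#' first row of each run; the assay type is derived from the assay code via
#' the dialect configuration.
#'
#' @param rows A `ptr_lab_export` data frame.
#' @param dialects A `ptr_dialects` object.
#' @param dialect Dialect id; defaults to the one recorded on `rows`.
#' @return A data frame of class `ptr_epr` with one row per submission:
#'   `lab_no`, `recd`, `species`, `breed`, `gender`, `practice_id`,
#'   `assay_type`, `report_text`, `lab_dialect`.
#' @export
concatenate_submissions <- function(rows, dialects = load_dialects(),
                                    dialect = NULL) {
  if (is.null(dialect)) dialect <- attr(rows, "dialect")
  if (is.null(dialect)) dialect <- "lab_a"
  n <- nrow(rows)
  if (n == 0) {
    out <- data.frame(lab_no = character(0), recd = as.Date(character(0)),
                      species = character(0), breed = character(0),
                      gender = character(0), practice_id = character(0),
                      assay_type = character(0), report_text = character(0),
                      lab_dialect = character(0), stringsAsFactors = FALSE)
    class(out) <- c("ptr_epr", "data.frame")
    return(out)
  }
  r <- rle(rows$lab_no)
  if (anyDuplicated(r$values)) {
    dups <- unique(r$values[duplicated(r$values)])
    warning("non-adjacent repeats of sample reference(s) treated as ",
            "distinct submissions: ", paste(dups, collapse = ", "))
  }
  run <- rep(seq_along(r$lengths), r$lengths)
  first <- which(!duplicated(run))
  report_text <- vapply(split(rows$rescomment, run),
                        paste, character(1), collapse = "\n")
  # species conflicts within a run: warn, keep first value
  conflict <- vapply(split(rows$species, run), function(s) {
    s <- unique(trimws(tolower(s[nzchar(trimws(s))])))
    length(s) > 1
  }, logical(1))
  if (any(conflict)) {
    warning("conflicting species within submission(s) ",
            paste(r$values[conflict], collapse = ", "),
            "; first value kept")
  }
  out <- data.frame(
    lab_no = rows$lab_no[first],
    recd = rows$recd[first],
    species = rows$species[first],
    breed = rows$breed[first],
    gender = rows$gender[first],
    practice_id = rows$practice_id[first],
    assay_type = assay_type_from_code(rows$assay_code[first], dialects,
                                      dialect),
    report_text = unname(report_text),
    lab_dialect = dialect,
    stringsAsFactors = FALSE
  )
  unknown <- is.na(out$assay_type)
  if (any(unknown)) {
    warning(sum(unknown), " submission(s) with unrecognized assay code; ",
            "defaulting to histology")
    out$assay_type[unknown] <- "histology"
  }
  rownames(out) <- NULL
  class(out) <- c("ptr_epr", "data.frame")
  out
}

#' Canonical species label
#'
#' @param x Character vector of raw species labels.
#' @return `"canine"`, `"feline"`, or `NA` for anything else; matching is
#'   case- and whitespace-insensitive.
#' @export
normalize_species <- function(x) {
  k <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(k))
  out[k %in% c("canine", "dog", "dogs")] <- "canine"
  out[k %in% c("feline", "cat", "cats")] <- "feline"
  out
}

#' Filter records to dogs and cats
#'
#' A pure filter: surviving records are returned unaltered. Discards are
#' counted per raw species label and reported via `message()`.
#'
#' @param records A `ptr_epr` data frame.
#' @return The subset of `records` whose species normalizes to canine or
#'   feline.
#' @export
filter_species <- function(records) {
  keep <- !is.na(normalize_species(records$species))
  if (any(!keep)) {
    tab <- table(trimws(records$species[!keep]), useNA = "ifany")
    message("discarded ", sum(!keep), " record(s) by species: ",
            paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                  collapse = ", "))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
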