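#' Registry column names (schema columns A-O)
#' @export
registry_columns <- c(
  "ReportRef", "TumourRef", "ResultDate", "Species", "Breed", "Gender",
  "Anonymous_PracticeID", "Histo_Cyto", "Tumours_in_the_report",
  "Primary_tumour", "Grade_2_tier", "Grade_3_tier", "Differentiation",
  "Location", "Uncertainty_terms")

#' Assign tumour references within one report
#'
#' Registrable tumours of report `R.x` receive references `R.x-T.1`,
#' `R.x-T.2`, ... contiguously in lesion order.
#'
#' @param report_ref Report reference string.
#' @param annotations Data frame of registrable lesion annotations, ordered
#'   by `ordinal`.
#' @return `annotations` with a `tumour_ref` column prepended.
#' @export
assign_tumour_refs <- function(report_ref, annotations) {
  stopifnot(length(report_ref) == 1, nzchar(report_ref))
  n <- nrow(annotations)
  if (n > 0 && is.unsorted(annotations$ordinal)) {
    stop("lesions must be ordered by ordinal")
  }
  cbind(data.frame(tumour_ref = if (n) paste0(report_ref, "-T.", seq_len(n))
                   else character(0),
                   stringsAsFactors = FALSE),
        annotations)
}

.empty_registry <- function() {
  out <- data.frame(
    ReportRef = character(0), TumourRef = character(0),
    ResultDate = character(0), Species = character(0), Breed = character(0),
    Gender = character(0), Anonymous_PracticeID = character(0),
    Histo_Cyto = character(0), Tumours_in_the_report = integer(0),
    Primary_tumour = character(0), Grade_2_tier = character(0),
    Grade_3_tier = character(0), Differentiation = character(0),
    Location = character(0), Uncertainty_terms = character(0),
    stringsAsFactors = FALSE)
  class(out) <- c("ptr_registry", "data.frame")
  out
}

#' Merge animal and tumour tables into the 15-column registry
#'
#' Inner join on the report reference; every tumour row must have a matching
#' animal row (an orphan reference is a hard error listing the offenders).
#' Output columns are exactly the schema columns A-O, one row per tumour,
#' with `Tumours_in_the_report` recomputed as the number of rows sharing the
#' reference.
#'
#' @param animal_rows Data frame keyed by `ReportRef` with columns
#'   `ResultDate`, `Species`, `Breed`, `Gender`, `Anonymous_PracticeID`,
#'   `Histo_Cyto`.
#' @param tumour_rows Data frame keyed by `ReportRef` with columns
#'   `TumourRef`, `Primary_tumour`, `Grade_2_tier`, `Grade_3_tier`,
#'   `Differentiation`, `Location`, `Uncertainty_terms`.
#' @return A data frame of class `ptr_registry`.
#' @export
merge_animal_tumour <- function(animal_rows, tumour_rows) {
  if (nrow(tumour_rows) == 0) return(.empty_registry())
  if (anyDuplicated(animal_rows$ReportRef)) {
    stop("duplicate report references in the animal table")
  }
  orphans <- setdiff(tumour_rows$ReportRef, animal_rows$ReportRef)
  if (length(orphans)) {
    stop("tumour rows with no matching animal row: ",
         paste(orphans, collapse = ", "))
  }
  i <- match(tumour_rows$ReportRef, animal_rows$ReportRef)
  counts <- table(tumour_rows$ReportRef)
  blank <- function(x) ifelse(is.na(x), "", x)
  out <- data.frame(
    ReportRef = tumour_rows$ReportRef,
    TumourRef = tumour_rows$TumourRef,
    ResultDate = blank(animal_rows$ResultDate[i]),
    Species = animal_rows$Species[i],
    Breed = animal_rows$Breed[i],
    Gender = animal_rows$Gender[i],
    Anonymous_PracticeID = animal_rows$Anonymous_PracticeID[i],
    Histo_Cyto = animal_rows$Histo_Cyto[i],
    Tumours_in_the_report =
      as.integer(counts[tumour_rows$ReportRef]),
    Primary_tumour = tumour_rows$Primary_tumour,
    Grade_2_tier = blank(tumour_rows$Grade_2_tier),
    Grade_3_tier = blank(tumour_rows$Grade_3_tier),
    Differentiation = blank(tumour_rows$Differentiation),
    Location = blank(tumour_rows$Location),
    Uncertainty_terms = blank(tumour_rows$Uncertainty_terms),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ptr_registry", "data.frame")
  out
}

#' Validate registry invariants
#'
#' Checks the 15-column schema and order, the `R.x-T.n` reference pattern
#' with contiguous ordinals, the per-report tumour counts, and that every
#' row carries a non-empty tumour type.
#'
#' @param table A registry data frame.
#' @return Invisibly `TRUE`; errors describe the first violation found.
#' @export
validate_registry <- function(table) {
  if (!identical(names(table), registry_columns)) {
    stop("registry must have exactly the 15 schema columns in order A-O")
  }
  if (nrow(table) == 0) return(invisible(TRUE))
  if (any(is.na(table$Primary_tumour) | !nzchar(table$Primary_tumour))) {
    stop("registry rows must have a non-empty Primary_tumour")
  }
  expect_ref <- unlist(lapply(split(table$ReportRef, table$ReportRef),
                              function(r) paste0(r, "-T.", seq_along(r))))
  got <- unlist(split(table$TumourRef, table$ReportRef))
  if (!identical(unname(got), unname(expect_ref))) {
    stop("tumour references must be <ReportRef>-T.<n> with contiguous n")
  }
  counts <- table(table$ReportRef)
  if (any(table$Tumours_in_the_report !=
          as.integer(counts[table$ReportRef]))) {
    stop("Tumours_in_the_report must equal the number of rows per report")
  }
  invisible(TRUE)
}

#' Write a registry to disk
#'
#' CSV output uses RFC-4180 quoting, UTF-8 and ISO dates; `jsonl` writes one
#' JSON object with the 15 schema keys per line. Output is bit-stable for a
#' fixed input and round-trips through [read_registry()].
#'
#' @param table A registry data frame (validated first).
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return Invisibly `path`.
#' @export
write_registry <- function(table, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  validate_registry(table)
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(table))) {
      writeLines(jsonlite::toJSON(as.list(table[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a registry written by [write_registry()]
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer.
#' @return A `ptr_registry` data frame.
#' @export
read_registry <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  }
  if (format == "csv") {
    out <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8")
  } else {
    rows <- lapply(readLines(path, encoding = "UTF-8", warn = FALSE),
                   function(l) {
                     x <- jsonlite::fromJSON(l)
                     x[vapply(x, is.null, TRUE)] <- ""
                     as.data.frame(x, stringsAsFactors = FALSE)
                   })
    out <- do.call(rbind, rows)
  }
  out <- out[, registry_columns]
  out$Tumours_in_the_report <- as.integer(out$Tumours_in_the_report)
  class(out) <- c("ptr_registry", "data.frame")
  out
}
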