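# End-to-end registry construction: ingest -> sections -> lesions ->
# classifiers -> normalization -> merge.

# Normalize one raw annotation data frame into registry-form fields.
.normalize_annotations <- function(ann, lexicons, maps) {
  loc_surface <- ann$location
  # adjective/noun pairings recorded on the location lexicon feed the map
  lex_map <- lexicons$location
  carried <- lex_map$maps_to[match(tolower(loc_surface),
                                   tolower(lex_map$surface))]
  loc_surface <- ifelse(!is.na(carried), carried, loc_surface)
  g3 <- normalize_term(ann$grade_3_tier, maps$grade)
  data.frame(
    ordinal = ann$ordinal,
    Primary_tumour = normalize_term(ann$primary_tumour, maps$tumour_type),
    Grade_2_tier = normalize_term(ann$grade_2_tier, maps$grade),
    Grade_3_tier = sub("^grade ", "", g3),
    Differentiation = normalize_term(ann$differentiation,
                                     maps$differentiation),
    Location = normalize_term(loc_surface, maps$location),
    Uncertainty_terms = ann$uncertainty,
    stringsAsFactors = FALSE)
}

#' Run extraction and classification for one EPR record
#'
#' Cleans markup, locates the section keywords for the record's dialect and
#' assay type, extracts the diagnosis span and ranked location sources,
#' splits the span into lesions, applies the six lexicons to each lesion,
#' drops non-registrable lesions, and normalizes the surviving annotations.
#'
#' @param record A list or one-row `ptr_epr` data frame.
#' @param dialects,lexicons,maps Configuration objects (see
#'   [load_dialects()], [load_lexicons()], [load_normalization_maps()]).
#' @return Data frame of normalized tumour rows for the record (possibly
#'   zero rows) with columns `ordinal`, `Primary_tumour`, `Grade_2_tier`,
#'   `Grade_3_tier`, `Differentiation`, `Location`, `Uncertainty_terms`.
#' @export
process_record <- function(record, dialects = load_dialects(),
                           lexicons = load_lexicons(),
                           maps = load_normalization_maps()) {
  kw <- dialect_keywords(dialects, record$lab_dialect[[1]],
                         record$assay_type[[1]])
  text <- normalize_markup(record$report_text[[1]])
  sp <- .section_spans(text, kw)
  lesions <- split_lesions(sp$diagnosis_text)
  none <- .normalize_annotations(
    data.frame(ordinal = integer(0), primary_tumour = character(0),
               grade_2_tier = character(0), grade_3_tier = character(0),
               differentiation = character(0), uncertainty = character(0),
               location = character(0), stringsAsFactors = FALSE),
    lexicons, maps)
  if (nrow(lesions) == 0) return(none)
  cand <- data.frame(rank = 2:3,
                     text = c(sp$clinical_history_text, sp$histology_text),
                     stringsAsFactors = FALSE)
  cand <- cand[nzchar(cand$text), , drop = FALSE]
  anns <- do.call(rbind, lapply(seq_len(nrow(lesions)), function(i) {
    annotate_lesion(lesions$text[i], cand, lexicons)
  }))
  anns$ordinal <- lesions$ordinal
  keep <- vapply(seq_len(nrow(anns)), function(i) {
    is_registrable_tumour(anns[i, , drop = FALSE], lexicons$primary_tumour)
  }, logical(1))
  anns <- anns[keep, , drop = FALSE]
  if (nrow(anns) == 0) return(none)
  anns$ordinal <- seq_len(nrow(anns))
  .normalize_annotations(anns, lexicons, maps)
}

.cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Build the 15-column tumour registry
#'
#' The full pipeline: read (or accept) a laboratory export, concatenate
#' multi-row submissions, filter to dogs and cats, extract/classify/normalize
#' every report, assign tumour references, and merge animal and tumour data.
#' Reports yielding no registrable tumour contribute no rows.
#'
#' @param input A path to an export file, a `ptr_lab_export` data frame, or
#'   a `ptr_epr` data frame of concatenated records.
#' @param dialect Laboratory dialect id (used when `input` is a path).
#' @param dialects,lexicons,maps Configuration objects.
#' @param min_count When greater than zero, run [apply_aggregation()] with
#'   this occurrence threshold after assembly.
#' @return A `ptr_registry` data frame (columns A-O).
#' @export
build_registry <- function(input, dialect = "lab_a",
                           dialects = load_dialects(),
                           lexicons = load_lexicons(),
                           maps = load_normalization_maps(),
                           min_count = 0) {
  records <- if (inherits(input, "ptr_epr")) {
    input
  } else if (inherits(input, "ptr_lab_export")) {
    concatenate_submissions(input, dialects)
  } else if (is.character(input)) {
    concatenate_submissions(read_lab_export(input, dialect = dialect),
                            dialects)
  } else {
    stop("input must be a file path, a ptr_lab_export or a ptr_epr object")
  }
  records <- filter_species(records)
  if (nrow(records) == 0) return(.empty_registry())

  tumour_rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    rows <- process_record(rec, dialects, lexicons, maps)
    if (nrow(rows) == 0) next
    rows <- assign_tumour_refs(rec$lab_no, rows)
    rows$ReportRef <- rec$lab_no
    tumour_rows[[i]] <- rows
  }
  tumour_rows <- do.call(rbind, tumour_rows)
  if (is.null(tumour_rows) || nrow(tumour_rows) == 0) {
    return(.empty_registry())
  }
  g <- parse_gender(records$gender)
  animal_rows <- data.frame(
    ReportRef = records$lab_no,
    ResultDate = ifelse(is.na(records$recd), "",
                        format(records$recd, "%Y-%m-%d")),
    Species = .cap1(normalize_species(records$species)),
    Breed = normalize_breed(records$breed, normalize_species(records$species),
                            maps),
    Gender = format_gender(g$sex, g$neuter),
    Anonymous_PracticeID = records$practice_id,
    Histo_Cyto = .cap1(records$assay_type),
    stringsAsFactors = FALSE)
  names(tumour_rows)[names(tumour_rows) == "tumour_ref"] <- "TumourRef"
  out <- merge_animal_tumour(animal_rows, tumour_rows)
  if (min_count > 0) out <- apply_aggregation(out, min_count)
  validate_registry(out)
  out
}
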