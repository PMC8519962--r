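#' Load laboratory dialect configuration
#'
#' Each submitting laboratory uses slightly different section keywords and
#' assay codes. The dialect file is plain YAML with one block per laboratory,
#' holding an `assay_codes` map (assay type -> code substrings) and a
#' `keywords` block per assay type with the five section keyword lists
#' (`diagnosis_start`, `prognosis`, `clinical_history`, `histology`,
#' `comments`).
#'
#' @param path Path to a dialect YAML file. `NULL` loads the bundled defaults.
#' @return A named list of dialect configurations, class `ptr_dialects`.
#' @export
load_dialects <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dialects.yml", package = "ptrminer")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("dialect configuration file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0) stop("dialect configuration is empty: ", path)
  structure(cfg, class = "ptr_dialects")
}

.keyword_slots <- c("diagnosis_start", "prognosis", "clinical_history",
                    "histology", "comments")

#' Section keywords for one (laboratory, assay type) pair
#'
#' @param dialects A `ptr_dialects` object from [load_dialects()].
#' @param dialect Dialect id (name of a block in the configuration).
#' @param assay_type `"histology"` or `"cytology"`.
#' @return A named list of uppercase keyword phrase vectors, class
#'   `ptr_keywords`, with elements `diagnosis_start`, `prognosis`,
#'   `clinical_history`, `histology` and `comments`.
#' @export
dialect_keywords <- function(dialects, dialect, assay_type) {
  d <- dialects[[dialect]]
  if (is.null(d)) stop("unknown laboratory dialect: ", dialect)
  kw <- d$keywords[[assay_type]]
  if (is.null(kw)) {
    stop("dialect '", dialect, "' has no keywords for assay type '",
         assay_type, "'")
  }
  missing <- setdiff(.keyword_slots, names(kw))
  if (length(missing)) {
    stop("dialect '", dialect, "'/", assay_type,
         " is missing keyword lists: ", paste(missing, collapse = ", "))
  }
  kw <- lapply(kw[.keyword_slots], function(x) toupper(as.character(x)))
  if (any(vapply(kw, length, 1L) == 0L)) {
    stop("every keyword list must be non-empty")
  }
  structure(kw, class = "ptr_keywords")
}

#' Map an assay code to an assay type
#'
#' Codes are matched case-insensitively against the dialect's configured code
#' substrings (e.g. codes containing "CYT" mean cytology).
#'
#' @param code Character vector of laboratory assay codes.
#' @param dialects A `ptr_dialects` object.
#' @param dialect Dialect id.
#' @return Character vector: `"histology"`, `"cytology"`, or `NA` when no
#'   configured substring matches.
#' @export
assay_type_from_code <- function(code, dialects, dialect) {
  d <- dialects[[dialect]]
  if (is.null(d)) stop("unknown laboratory dialect: ", dialect)
  map <- d$assay_codes
  code_up <- toupper(trimws(as.character(code)))
  vapply(code_up, function(cd) {
    for (type in names(map)) {
      pats <- toupper(as.character(map[[type]]))
      if (any(vapply(pats, function(p) grepl(p, cd, fixed = TRUE), TRUE))) {
        return(type)
      }
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
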