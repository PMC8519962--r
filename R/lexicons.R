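#' Lexicon categories
#'
#' The six classifier look-up tables applied to each lesion.
#' @export
lexicon_categories <- c("primary_tumour", "grade_2_tier", "grade_3_tier",
                        "differentiation", "uncertainty", "location")

#' Read one ordered lexicon
#'
#' Format: UTF-8, one surface form per line, order = match priority (earlier
#' entries win; curators place specific phrases above generic capture terms).
#' Optional tab-separated flags: `excluded` marks non-neoplastic entries
#' (hamartomas, cysts, tumour-like lesions) that never enter the registry;
#' `maps_to=<preferred>` records an adjective/noun pairing resolved at
#' normalization time. Blank lines and lines starting with `#` are skipped.
#'
#' @param path Path to a lexicon file.
#' @param category One of [lexicon_categories].
#' @return A data frame of class `ptr_lexicon` with columns `surface`,
#'   `excluded` (logical) and `maps_to` (character, `NA` when absent), in
#'   file order, with attribute `category`.
#' @export
read_lexicon <- function(path, category = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  surface <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  flags <- lapply(parts, function(p) trimws(p[-1]))
  dup <- duplicated(tolower(surface))
  if (any(dup)) {
    stop("duplicate lexicon entries (after case-folding) in ", path, ": ",
         paste(unique(surface[dup]), collapse = ", "))
  }
  maps_to <- vapply(flags, function(f) {
    m <- f[startsWith(f, "maps_to=")]
    if (length(m)) sub("^maps_to=", "", m[1]) else NA_character_
  }, character(1))
  out <- data.frame(
    surface = surface,
    excluded = vapply(flags, function(f) "excluded" %in% f, logical(1)),
    maps_to = maps_to,
    stringsAsFactors = FALSE
  )
  attr(out, "category") <- category
  class(out) <- c("ptr_lexicon", "data.frame")
  out
}

#' Load the six bundled (or replacement) lexicons
#'
#' @param dir Directory holding `<category>.tsv` files for every category in
#'   [lexicon_categories]; `NULL` loads the bundled reduced lexicons.
#' @return Named list of `ptr_lexicon` objects, class `ptr_lexicons`.
#' @export
load_lexicons <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "lexicons", package = "ptrminer")
  }
  out <- lapply(lexicon_categories, function(cat) {
    read_lexicon(file.path(dir, paste0(cat, ".tsv")), category = cat)
  })
  names(out) <- lexicon_categories
  structure(out, class = "ptr_lexicons")
}

#' First-match lexicon search
#'
#' Walks the lexicon from the top and returns the first entry (by list order,
#' not by position in the text) that occurs case-insensitively as a substring
#' of `text`. Only a single match is ever recorded. No word-boundary
#' anchoring is applied, mirroring the spreadsheet-style nested search the
#' registry was built with; the resulting false-positive class is measurable
#' with the validation module.
#'
#' @param text A single string (the lesion or section text).
#' @param lexicon A non-empty `ptr_lexicon`.
#' @return The matched surface form exactly as stored in the lexicon, or
#'   `NA_character_`.
#' @export
first_match <- function(text, lexicon) {
  stopifnot(nrow(lexicon) > 0)
  if (length(text) != 1 || is.na(text) || !nzchar(text)) {
    return(NA_character_)
  }
  hits <- stringi::stri_detect_fixed(
    text, lexicon$surface,
    opts_fixed = stringi::stri_opts_fixed(case_insensitive = TRUE))
  i <- which(hits)
  if (length(i) == 0) NA_character_ else lexicon$surface[i[1]]
}

#' Annotate one lesion with the six classifiers
#'
#' Tumour type, both grading tiers, differentiation and uncertainty are
#' matched against the lesion text itself. Location is matched against the
#' lesion text first (the rank-1, diagnosis-adjacent source), then against
#' the rank-2 (clinical history) and rank-3 (histology) section spans; the
#' first source yielding a match wins and its rank is recorded.
#'
#' @param lesion A single string, or a list/one-row data frame with a `text`
#'   element.
#' @param location_candidates Data frame from [extract_location_candidates()]
#'   (only ranks 2 and 3 are consulted; rank 1 is the lesion text itself).
#' @param lexicons A `ptr_lexicons` list.
#' @return One-row data frame with columns `primary_tumour`, `grade_2_tier`,
#'   `grade_3_tier`, `differentiation`, `uncertainty`, `location` (matched
#'   surface forms or `NA`) and `location_source_rank` (integer or `NA`).
#' @export
annotate_lesion <- function(lesion, location_candidates = NULL, lexicons) {
  txt <- if (is.character(lesion)) lesion[[1]] else lesion$text[[1]]
  ann <- data.frame(
    primary_tumour = first_match(txt, lexicons$primary_tumour),
    grade_2_tier = first_match(txt, lexicons$grade_2_tier),
    grade_3_tier = first_match(txt, lexicons$grade_3_tier),
    differentiation = first_match(txt, lexicons$differentiation),
    uncertainty = first_match(txt, lexicons$uncertainty),
    location = NA_character_,
    location_source_rank = NA_integer_,
    stringsAsFactors = FALSE
  )
  sources <- list(`1` = txt)
  if (!is.null(location_candidates) && nrow(location_candidates)) {
    for (r in c(2L, 3L)) {
      hit <- location_candidates$text[location_candidates$rank == r]
      if (length(hit)) sources[[as.character(r)]] <- hit[[1]]
    }
  }
  for (r in names(sources)) {
    m <- first_match(sources[[r]], lexicons$location)
    if (!is.na(m)) {
      ann$location <- m
      ann$location_source_rank <- as.integer(r)
      break
    }
  }
  ann
}

#' Is an annotated lesion a registrable tumour?
#'
#' A lesion enters the registry only when its primary-tumour match is a
#' lexicon entry not flagged as excluded (hamartomas, cysts and tumour-like
#' masses carry the `excluded` flag and are dropped).
#'
#' @param annotation One-row data frame from [annotate_lesion()].
#' @param lexicon The primary-tumour `ptr_lexicon`.
#' @return `TRUE` or `FALSE`.
#' @export
is_registrable_tumour <- function(annotation, lexicon) {
  pt <- annotation$primary_tumour[[1]]
  if (is.na(pt)) return(FALSE)
  i <- match(tolower(pt), tolower(lexicon$surface))
  if (is.na(i)) return(FALSE)
  !lexicon$excluded[i]
}

#' Sample unmatched lesion texts for lexicon curation
#'
#' Supports the iterative lexicon-growth loop: after each matching round, a
#' seeded uniform sample (without replacement) of lesions still unmatched in
#' one category is drawn for human review, and newly identified terms are
#' added to the top of the lexicon; the loop stops when a full batch yields
#' no new terms.
#'
#' @param annotations Data frame holding a `text` column and one column per
#'   lexicon category (as produced by the pipeline before normalization).
#' @param category Column to test for unmatched (`NA`) entries.
#' @param n Maximum sample size (the curation protocol reads 200 at a time).
#' @param seed Integer seed; the same inputs and seed reproduce the sample.
#' @return Character vector of up to `n` lesion texts.
#' @export
sample_unmatched <- function(annotations, category, n = 200, seed = 1) {
  stopifnot(n >= 1, category %in% lexicon_categories)
  idx <- which(is.na(annotations[[category]]))
  if (length(idx) == 0) return(character(0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  take <- if (length(idx) <= n) sample(idx) else sample(idx, n)
  annotations$text[take]
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
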