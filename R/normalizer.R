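#' Read a surface-form to preferred-term map
#'
#' Two-column UTF-8 TSV (surface, preferred). Lookup is case-insensitive and
#' whitespace-trimmed; every preferred term is made a fixed point (rows
#' mapping a preferred term to itself are added when absent), so
#' normalization is idempotent.
#'
#' @param path Path to the map file.
#' @param domain Label recorded on the map (e.g. `"tumour_type"`).
#' @return A data frame of class `ptr_norm_map` with columns `surface`,
#'   `preferred` and the precomputed lookup `key`.
#' @export
read_normalization_map <- function(path, domain = NULL) {
  if (!file.exists(path)) stop("normalization map not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2
  if (any(bad)) stop("malformed map line(s) in ", path)
  out <- data.frame(
    surface = vapply(parts, function(p) trimws(p[[1]]), character(1)),
    preferred = vapply(parts, function(p) trimws(p[[2]]), character(1)),
    stringsAsFactors = FALSE
  )
  fp <- setdiff(tolower(unique(out$preferred)), tolower(out$surface))
  if (length(fp)) {
    add <- unique(out$preferred[tolower(out$preferred) %in% fp])
    out <- rbind(out, data.frame(surface = add, preferred = add,
                                 stringsAsFactors = FALSE))
  }
  out$key <- .norm_key(out$surface)
  attr(out, "domain") <- domain
  class(out) <- c("ptr_norm_map", "data.frame")
  out
}

.norm_key <- function(x) {
  stringi::stri_replace_all_regex(tolower(trimws(x)), "\\s+", " ")
}

#' Load the bundled normalization maps
#'
#' @param dir Directory with `tumour_type.tsv`, `grade.tsv`, `location.tsv`,
#'   `differentiation.tsv`, `breed_dog.tsv`, `breed_cat.tsv`; `NULL` loads
#'   the bundled set.
#' @return Named list of `ptr_norm_map` objects, class `ptr_norm_maps`.
#' @export
load_normalization_maps <- function(dir = NULL) {
  if (is.null(dir)) dir <- system.file("extdata", "maps", package = "ptrminer")
  domains <- c("tumour_type", "grade", "location", "differentiation",
               "breed_dog", "breed_cat")
  out <- lapply(domains, function(d) {
    read_normalization_map(file.path(dir, paste0(d, ".tsv")), domain = d)
  })
  names(out) <- domains
  structure(out, class = "ptr_norm_maps")
}

#' Normalize a surface form to its preferred term
#'
#' Exact lookup after case-folding and whitespace trimming. Unmapped surfaces
#' pass through unchanged (visible to the curation loop rather than silently
#' bucketed); `NA` stays `NA`.
#'
#' @param surface Character vector of matched surface forms.
#' @param map A `ptr_norm_map`.
#' @return Character vector of preferred terms.
#' @export
normalize_term <- function(surface, map) {
  stopifnot(nrow(map) > 0)
  i <- match(.norm_key(surface), map$key)
  out <- ifelse(is.na(i), trimws(surface), map$preferred[i])
  out[is.na(surface)] <- NA_character_
  out
}

#' Normalize a breed against the species' breed authority table
#'
#' Dog breeds follow the FCI/AKC naming, cat breeds FIFE/TICA, augmented by
#' popular hybrids; the bundled tables are editable skeletons. Empty or
#' explicitly unknown surfaces become `"unknown"`; unmapped non-empty
#' surfaces pass through unchanged.
#'
#' @param surface Character vector of raw breed strings.
#' @param species `"canine"` or `"feline"` (recycled).
#' @param maps A `ptr_norm_maps` list.
#' @return Character vector of preferred breed names.
#' @export
normalize_breed <- function(surface, species, maps = load_normalization_maps()) {
  species <- rep_len(species, length(surface))
  out <- character(length(surface))
  for (i in seq_along(surface)) {
    s <- trimws(surface[i])
    if (is.na(surface[i]) || !nzchar(s) ||
        tolower(s) %in% c("unknown", "?", "not recorded", "n/a", "na")) {
      out[i] <- "unknown"
      next
    }
    map <- if (identical(species[i], "feline")) maps$breed_cat else maps$breed_dog
    out[i] <- normalize_term(s, map)
  }
  out
}

#' Parse a raw gender field into sex and neuter status
#'
#' Laboratory gender strings combine sex and neuter status (e.g. "Female
#' entire", "Male neutered"). Unrecognized tokens yield `"unknown"`.
#'
#' @param surface Character vector of raw gender phrases.
#' @return Data frame with columns `sex` (`female`/`male`/`unknown`) and
#'   `neuter` (`entire`/`neutered`/`unknown`).
#' @export
parse_gender <- function(surface) {
  s <- tolower(trimws(as.character(surface)))
  sex <- rep("unknown", length(s))
  sex[grepl("\\bf(emale)?\\b", s)] <- "female"
  sex[grepl("(?<!fe)\\bm(ale)?\\b", s, perl = TRUE) & sex == "unknown"] <- "male"
  sex[grepl("\\bmale\\b", s) & !grepl("female", s)] <- "male"
  neuter <- rep("unknown", length(s))
  neuter[grepl("neuter|spayed|castrat", s)] <- "neutered"
  neuter[grepl("entire|intact", s)] <- "entire"
  data.frame(sex = sex, neuter = neuter, stringsAsFactors = FALSE)
}

#' Render sex + neuter status as a registry gender label
#'
#' @param sex,neuter Vectors as returned by [parse_gender()].
#' @return Labels like `"Female entire"`, `"Male"`, or `"unknown"`.
#' @export
format_gender <- function(sex, neuter) {
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  out <- character(length(sex))
  for (i in seq_along(sex)) {
    out[i] <- if (sex[i] == "unknown" && neuter[i] == "unknown") {
      "unknown"
    } else if (neuter[i] == "unknown") {
      cap(sex[i])
    } else if (sex[i] == "unknown") {
      cap(neuter[i])
    } else {
      paste(cap(sex[i]), neuter[i])
    }
  }
  out
}

.load_lines <- function(file) {
  path <- system.file("extdata", "maps", file, package = "ptrminer")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
}

#' Named aggregation map (e.g. plasmacytoma -> Plasma cell tumour)
#' @return A `ptr_norm_map`.
#' @export
load_aggregations <- function() {
  read_normalization_map(
    system.file("extdata", "maps", "aggregations.tsv", package = "ptrminer"),
    domain = "aggregation")
}

#' Tumour types that stand alone in the registry
#' @return Character vector of preferred terms common enough to keep their
#'   own registry category.
#' @export
load_standalone_terms <- function() {
  trimws(.load_lines("standalone_terms.txt"))
}

# catch-all routing for rare or generically-described types, checked in order
.catchall_rules <- list(
  c("epithelioma", "Epithelioma_others"),
  c("epithelial", "Epithelial tumour_others"),
  c("carcinoma", "Carcinoma_others"),
  c("adenoma", "Adenoma_others"),
  c("sarcoma|mesenchymal|fibroma|myxoma|blastoma|histiocyt|lipoma",
    "Mesenchymal_neoplasias_others")
)

#' Catch-all or named-aggregate category for a tumour type
#'
#' Named aggregations (plasma cell tumours) are applied first; types on the
#' standalone list keep their own category (`NA` returned); anything else is
#' routed to one of the six catch-all categories by morphology keywords,
#' falling back to `Neoplasia_Tumours_others`.
#'
#' @param preferred Character vector of preferred tumour types.
#' @param aggregations A `ptr_norm_map` of named aggregations.
#' @param standalone Character vector of standalone types.
#' @return Character vector: aggregate label or `NA` where the type stands
#'   alone.
#' @export
assign_aggregate <- function(preferred,
                             aggregations = load_aggregations(),
                             standalone = load_standalone_terms()) {
  vapply(preferred, function(p) {
    if (is.na(p)) return(NA_character_)
    i <- match(.norm_key(p), aggregations$key)
    if (!is.na(i) && aggregations$preferred[i] != p) {
      return(aggregations$preferred[i])
    }
    if (tolower(p) %in% tolower(standalone)) return(NA_character_)
    low <- tolower(p)
    for (rule in .catchall_rules) {
      if (grepl(rule[1], low)) return(rule[2])
    }
    "Neoplasia_Tumours_others"
  }, character(1), USE.NAMES = FALSE)
}

#' Corpus-level aggregation pass over a registry
#'
#' Replaces tumour types occurring fewer than `min_count` times with their
#' catch-all category, and applies the named aggregations throughout. The
#' threshold is a property of the corpus, not of single reports, which is why
#' this is a separate post-pass rather than part of per-report normalization.
#'
#' @param registry A registry data frame (see [merge_animal_tumour()]).
#' @param min_count Occurrence threshold below which a type is aggregated
#'   (the registry's published convention is 10); `0` disables rare-type
#'   aggregation while still applying named aggregations.
#' @param aggregations,standalone See [assign_aggregate()].
#' @return The registry with `Primary_tumour` relabelled; no rows are added
#'   or dropped.
#' @export
apply_aggregation <- function(registry, min_count = 10,
                              aggregations = load_aggregations(),
                              standalone = load_standalone_terms()) {
  pt <- registry$Primary_tumour
  counts <- table(pt)
  new <- vapply(pt, function(p) {
    i <- match(.norm_key(p), aggregations$key)
    if (!is.na(i) && aggregations$preferred[i] != p) {
      return(aggregations$preferred[i])
    }
    if (min_count > 0 && counts[[p]] < min_count) {
      agg <- assign_aggregate(p, aggregations,
                              standalone = character(0))
      if (!is.na(agg)) return(agg)
    }
    p
  }, character(1), USE.NAMES = FALSE)
  registry$Primary_tumour <- new
  registry
}
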