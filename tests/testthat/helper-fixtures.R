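# Shared fixtures and independent brute-force oracles.

fixture_export <- function() {
  system.file("extdata", "table1_export.csv", package = "ptrminer")
}

the_dialects <- load_dialects()
the_lexicons <- load_lexicons()
the_maps <- load_normalization_maps()
kw_histo <- dialect_keywords(the_dialects, "lab_a", "histology")

fixture_report_text <- function() {
  rows <- read_lab_export(fixture_export())
  concatenate_submissions(rows, the_dialects)$report_text[1]
}

# Oracle for locate_keyword: test every starting offset of every phrase.
oracle_locate <- function(text, phrases) {
  lt <- tolower(text)
  best <- NA_integer_
  for (p in tolower(phrases)) {
    np <- nchar(p)
    if (np == 0 || np > nchar(lt)) next
    for (s in seq_len(nchar(lt) - np + 1)) {
      if (substr(lt, s, s + np - 1) == p) {
        if (is.na(best) || s < best) best <- s
        break
      }
    }
  }
  best
}

# Oracle for first_match: walk entries in order, substring test per entry.
oracle_first_match <- function(text, lexicon) {
  lt <- tolower(text)
  for (i in seq_len(nrow(lexicon))) {
    e <- tolower(lexicon$surface[i])
    np <- nchar(e)
    if (np == 0 || np > nchar(lt)) next
    found <- FALSE
    for (s in seq_len(nchar(lt) - np + 1)) {
      if (substr(lt, s, s + np - 1) == e) { found <- TRUE; break }
    }
    if (found) return(lexicon$surface[i])
  }
  NA_character_
}

make_lab_rows <- function(lab_no, rescomment, species = "Canine",
                          assay_code = "HISTO") {
  n <- length(lab_no)
  out <- data.frame(
    lab_no = lab_no, recd = as.Date("2018-05-09"), recd_raw = "09/05/18",
    species = rep_len(species, n), breed = "Labrador retriever",
    gender = "Female entire", practice_id = "P001",
    assay_code = rep_len(assay_code, n),
    rescomment = rescomment, stringsAsFactors = FALSE)
  attr(out, "dialect") <- "lab_a"
  class(out) <- c("ptr_lab_export", "data.frame")
  out
}

random_word <- function(n = 1, min_len = 2, max_len = 8) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}
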