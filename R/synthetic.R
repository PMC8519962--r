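# Synthetic EPR generator with gold annotations. The generation vocabulary is
# a closed world drawn from the bundled lexicons and maps, so on a clean
# corpus a correct pipeline recovers the gold annotations exactly and any
# miss is a pipeline bug, not a data gap.

# Tumour types used for generation: surface written in the report, preferred
# registry term, and which grading tier (if any) plausibly accompanies them.
.gen_tumours <- data.frame(
  surface = c("Lipoma", "MCT", "Mast cell tumour", "Lymphoma", "Histiocytoma",
              "Squamous cell carcinoma", "Melanoma", "Osteosarcoma",
              "Seminoma", "Basal cell tumour", "Soft tissue sarcoma",
              "Fibrosarcoma", "Haemangiosarcoma"),
  preferred = c("Lipoma", "Mast cell tumour", "Mast cell tumour", "Lymphoma",
                "Histiocytoma", "Squamous cell carcinoma", "Melanoma",
                "Osteosarcoma", "Seminoma", "Basal cell tumour",
                "Soft tissue sarcoma", "Fibrosarcoma", "Haemangiosarcoma"),
  tier = c("none", "both", "both", "two", "none", "none", "none", "none",
           "none", "none", "three", "three", "none"),
  weight = c(22, 7, 6, 10, 8, 11, 6, 4, 3, 5, 8, 5, 5),
  stringsAsFactors = FALSE)

.gen_locations <- data.frame(
  surface = c("forelimb", "hindlimb", "neck", "thorax", "abdomen",
              "mammary gland", "spleen", "oral cavity", "axilla", "skin"),
  preferred = c("Forelimb", "Hindlimb", "Neck", "Thorax", "Abdomen",
                "Mammary gland", "Spleen", "Oral cavity", "Axilla", "Skin"),
  stringsAsFactors = FALSE)

# uncertainty phrasings: prefix forms precede the diagnosis, suffix forms
# trail it after a comma
.gen_uncertainty <- data.frame(
  surface = c("Consistent with", "Compatible with", "highly likely",
              "probable", "possible"),
  preferred = c("Consistent with", "Compatible with", "Highly likely",
                "Probable", "Possible"),
  prefix = c(TRUE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE)

.gen_differentiation <- data.frame(
  surface = c("Malignant", "benign", "well differentiated",
              "poorly differentiated"),
  preferred = c("Malignant", "Benign", "Well differentiated",
                "Poorly differentiated"),
  prefix = c(TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE)

.gen_grade2 <- data.frame(
  surface = c("Low-grade", "High-grade", "Low grade", "High grade"),
  preferred = c("Low-grade", "High-grade", "Low-grade", "High-grade"),
  stringsAsFactors = FALSE)

.gen_grade3 <- data.frame(
  surface = c("grade 1", "grade 2", "grade 3", "grade I", "grade II",
              "grade III", "second grade"),
  preferred = c("1", "2", "3", "1", "2", "3", "2"),
  stringsAsFactors = FALSE)

.gen_breeds <- list(
  canine = c("Labrador Retriever", "Retriever, Labrador", "Crossbreed",
             "Staffordshire bull terrier", "Cocker spaniel", "Labradoodle",
             "unknown"),
  feline = c("Domestic Short Hair", "DSH", "Domestic longhair",
             "British blue", "Maine coon", "unknown"))

.gen_genders <- c("Female entire", "Female neutered", "Male entire",
                  "Male neutered", "Female", "Male", "unknown")

# pairs used by reason-4 (location confusion) and reason-5 (generalization)
.reason4_pairs <- data.frame(
  written = c("Hepatoid (perianal) carcinoma", "Epithelial neoplasia in the abdomen"),
  predicted = c("Hepatoid carcinoma", "Epithelial tumour"),
  gold = c("Anal sac carcinoma", "Thyroid neoplasia"),
  stringsAsFactors = FALSE)

.reason5_pairs <- data.frame(
  written = c("Mesenchymal neoplasia", "Thyroid epithelial neoplasia"),
  gold = c("Soft tissue sarcoma", "Thyroid carcinoma"),
  stringsAsFactors = FALSE)

# portable (seed, index) keying for per-report determinism; kept below 2^31
.report_seed <- function(seed, index, salt = 0) {
  as.integer((as.numeric(seed) %% 65011 * 30011 + index * 613 +
                salt * 7919) %% 2147483629)
}

#' Specify a synthetic EPR corpus
#'
#' Defaults mirror the registry's published composition: 8.4% of reports
#' feline, 36.6% cytology, and a lesion-count distribution with median 1
#' derived from the registry's per-report tumour counts. Failure-mode rates
#' (the five misdiagnosis mechanisms) default to zero; they are mutually
#' exclusive per report.
#'
#' @param n_reports Number of reports.
#' @param p_cytology Proportion of cytology reports.
#' @param p_feline Proportion of feline reports.
#' @param lesion_count_probs Probabilities over 1..6 lesions per report.
#' @param dialect_mix Named proportions over laboratory dialects.
#' @param failure_rates Numeric length-5 vector, per-report probability of
#'   injecting misdiagnosis reasons 1..5.
#' @param p_multirow Proportion of submissions delivered as several
#'   consecutive export rows requiring concatenation.
#' @param seed Integer seed; together with the report index it determines
#'   every report byte-for-byte.
#' @return A validated list of class `ptr_corpus_spec`.
#' @export
corpus_spec <- function(n_reports = 400,
                        p_cytology = 0.366,
                        p_feline = 0.084,
                        lesion_count_probs = c(82479, 8452, 2022, 620, 242,
                                               126) / 93941,
                        dialect_mix = c(lab_a = 0.6, lab_b = 0.4),
                        failure_rates = c(0, 0, 0, 0, 0),
                        p_multirow = 0.3,
                        seed = 1) {
  stopifnot(n_reports >= 1, length(lesion_count_probs) == 6,
            length(failure_rates) == 5)
  if (abs(sum(lesion_count_probs) - 1) > 1e-9) {
    stop("lesion_count_probs must sum to 1")
  }
  if (abs(sum(dialect_mix) - 1) > 1e-9) stop("dialect_mix must sum to 1")
  if (any(failure_rates < 0) || sum(failure_rates) > 1) {
    stop("failure_rates must be in [0,1] and sum to at most 1")
  }
  structure(list(n_reports = as.integer(n_reports),
                 p_cytology = p_cytology, p_feline = p_feline,
                 lesion_count_probs = lesion_count_probs,
                 dialect_mix = dialect_mix,
                 failure_rates = as.numeric(failure_rates),
                 p_multirow = p_multirow, seed = as.integer(seed)),
            class = "ptr_corpus_spec")
}

# compose one lesion line plus its gold registry-form fields
.gen_lesion <- function(allow_extras = TRUE) {
  t <- .gen_tumours[sample(nrow(.gen_tumours), 1,
                           prob = .gen_tumours$weight), ]
  gold <- list(primary = t$preferred, grade2 = "", grade3 = "",
               differentiation = "", uncertainty = "", location = "")
  pre <- character(0)
  post <- character(0)
  if (allow_extras && t$tier != "none" && stats::runif(1) < 0.35) {
    use2 <- t$tier == "two" || (t$tier == "both" && stats::runif(1) < 0.5)
    if (use2) {
      g <- .gen_grade2[sample(nrow(.gen_grade2), 1), ]
      pre <- c(pre, g$surface)
      gold$grade2 <- g$preferred
    } else {
      g <- .gen_grade3[sample(nrow(.gen_grade3), 1), ]
      post <- c(post, paste0("(", g$surface, ")"))
      gold$grade3 <- g$preferred
    }
  }
  if (allow_extras && stats::runif(1) < 0.25) {
    u <- .gen_uncertainty[sample(nrow(.gen_uncertainty), 1), ]
    gold$uncertainty <- u$preferred
    if (u$prefix) pre <- c(u$surface, pre) else post <- c(post, paste0(", ", u$surface))
  }
  if (allow_extras && stats::runif(1) < 0.2) {
    d <- .gen_differentiation[sample(nrow(.gen_differentiation), 1), ]
    gold$differentiation <- d$preferred
    if (d$prefix) pre <- c(pre, d$surface) else post <- c(post, paste0(", ", d$surface))
  }
  if (allow_extras && stats::runif(1) < 0.85) {
    if (stats::runif(1) < 0.15) {
      pre <- c(pre, "cutaneous")
      gold$location <- "Skin"
    } else {
      l <- .gen_locations[sample(nrow(.gen_locations), 1), ]
      post <- c(post, paste0(", ", l$surface))
      gold$location <- l$preferred
    }
  }
  text <- paste0(paste(c(pre, t$surface), collapse = " "),
                 paste(post, collapse = ""))
  list(text = text, gold = gold)
}

.assemble_sections <- function(assay_type, diagnosis_section, with_prognosis,
                               joiner) {
  ch <- "Mass removed at routine visit and submitted for evaluation."
  if (assay_type == "histology") {
    parts <- c("DIAGNOSIS", diagnosis_section,
               if (with_prognosis) c("PROGNOSIS", "Guarded"),
               "CLINICAL HISTORY", ch,
               "HISTOLOGY", "Specimens processed and evaluated.",
               "COMMENTS", "None.")
  } else {
    parts <- c("CYTOLOGICAL INTERPRETATION", diagnosis_section,
               "CLINICAL HISTORY", ch,
               "CYTOLOGICAL DESCRIPTION", "Smears of adequate cellularity.",
               "COMMENTS", "None.")
  }
  paste(parts, collapse = joiner)
}

#' Generate one synthetic gold-annotated report
#'
#' Deterministic given `(spec$seed, index)`. The report text is assembled
#' from the dialect's section template with numeric or alphabetic lesion
#' delimiters; the gold annotations are what a perfect extractor should
#' produce. When `reason` is given the report is corrupted by
#' [inject_failure()] after generation.
#'
#' @param spec A `ptr_corpus_spec`.
#' @param index Report index (1-based).
#' @param reason Optional misdiagnosis reason 1..5 to inject.
#' @return A list of class `ptr_gold_report`: submission metadata, the
#'   assembled `report_text`, the `lesions` gold data frame and
#'   `injected_reason` (`NA` when clean).
#' @export
generate_report <- function(spec, index, reason = NA) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.report_seed(spec$seed, index))
  species <- if (stats::runif(1) < spec$p_feline) "feline" else "canine"
  assay <- if (stats::runif(1) < spec$p_cytology) "cytology" else "histology"
  n_lesions <- sample(1:6, 1, prob = spec$lesion_count_probs)
  if (!is.na(reason)) {
    if (reason %in% c(1, 3, 4, 5)) n_lesions <- 1L
    if (reason == 1) assay <- "cytology"
    if (reason == 2 && n_lesions < 2) {
      n_lesions <- sample(2:4, 1)
    }
  }
  dialect <- sample(names(spec$dialect_mix), 1, prob = spec$dialect_mix)
  lesions <- lapply(seq_len(n_lesions), function(i) .gen_lesion())
  if (!is.na(reason) && reason == 1) {
    lesions <- list(list(text = "Lipoma", gold = list(
      primary = "Lipoma", grade2 = "", grade3 = "", differentiation = "",
      uncertainty = "", location = "")))
  }
  texts <- vapply(lesions, function(l) l$text, character(1))
  if (n_lesions == 1) {
    diag_sec <- texts
  } else if (stats::runif(1) < 0.8) {
    diag_sec <- paste(paste0(seq_len(n_lesions), ". ", texts),
                      collapse = "\n")
  } else {
    diag_sec <- paste(paste0(LETTERS[seq_len(n_lesions)], ". ", texts),
                      collapse = "\n")
  }
  gold <- do.call(rbind, lapply(seq_along(lesions), function(i) {
    g <- lesions[[i]]$gold
    data.frame(ordinal = i, Primary_tumour = g$primary,
               Grade_2_tier = g$grade2, Grade_3_tier = g$grade3,
               Differentiation = g$differentiation, Location = g$location,
               Uncertainty_terms = g$uncertainty, stringsAsFactors = FALSE)
  }))
  joiner <- if (dialect == "lab_b") " <br> " else "\n"
  rep_obj <- structure(list(
    lab_no = sprintf("R.%d", 100000L + index),
    recd = as.Date("2018-04-01") + sample(0:425, 1),
    species = if (species == "canine") "Canine" else "Feline",
    breed = sample(.gen_breeds[[species]], 1),
    gender = sample(.gen_genders, 1),
    practice_id = sprintf("P%03d", sample.int(250, 1)),
    assay_code = if (assay == "histology") {
      sample(c("HISTO", "HISTO-STD"), 1)
    } else {
      sample(c("CYT", "CYT-FNA"), 1)
    },
    assay_type = assay,
    lab_dialect = dialect,
    joiner = joiner,
    with_prognosis = stats::runif(1) > 0.3,
    diagnosis_section = diag_sec,
    lesions = gold,
    injected_reason = NA_integer_
  ), class = "ptr_gold_report")
  rep_obj$report_text <- .assemble_sections(assay, diag_sec,
                                            rep_obj$with_prognosis, joiner)
  if (!is.na(reason)) {
    rep_obj <- inject_failure(rep_obj, reason,
                              seed = .report_seed(spec$seed, index, salt = 1))
  }
  rep_obj
}

#' Corrupt a gold report by one of the five misdiagnosis mechanisms
#'
#' Rewrites the diagnosis section so that the default pipeline is expected to
#' err while the gold annotations carry the expert answer:
#' reason 1 — a lipoma described as aspiration of fatty material without the
#' word "lipoma"; reason 2 — multiple identical tumours written without
#' delimiters ("Seminoma in both testicles" style), gold keeps all of them;
#' reason 3 — a hedged differential ("Lymphoma not excluded"), gold is
#' non-tumour; reason 4 — a location-confused diagnosis (hepatoid vs anal
#' sac carcinoma); reason 5 — the written diagnosis is a generic ancestor of
#' the gold type (mesenchymal neoplasia for soft tissue sarcoma).
#'
#' @param report A `ptr_gold_report`.
#' @param reason Integer 1..5.
#' @param seed Seed for the mechanism's internal choices.
#' @return The corrupted `ptr_gold_report` with `injected_reason` set.
#' @export
inject_failure <- function(report, reason, seed = 1) {
  stopifnot(inherits(report, "ptr_gold_report"), reason %in% 1:5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(report$lesions)
  gold1 <- function(primary, location = "") {
    data.frame(ordinal = 1L, Primary_tumour = primary, Grade_2_tier = "",
               Grade_3_tier = "", Differentiation = "", Location = location,
               Uncertainty_terms = "", stringsAsFactors = FALSE)
  }
  if (reason == 1) {
    if (n != 1 || report$lesions$Primary_tumour[1] != "Lipoma" ||
        report$assay_type != "cytology") {
      stop("reason 1 needs a single-lesion cytology lipoma report")
    }
    report$diagnosis_section <- sample(
      c("Aspiration of adipose tissue.", "Fat tissue aspiration.",
        "Aspiration of lipid material."), 1)
    report$lesions <- gold1("Lipoma")
  } else if (reason == 2) {
    if (n < 2) stop("reason 2 needs at least two lesions")
    type <- report$lesions$Primary_tumour[1]
    surface <- .gen_tumours$surface[match(type, .gen_tumours$preferred)]
    report$diagnosis_section <- if (n == 2) {
      sprintf("%s in both sites sampled.", surface)
    } else {
      sprintf("All %d sites: %s.", n, surface)
    }
    report$lesions <- do.call(rbind, lapply(seq_len(n), function(i) {
      g <- gold1(type); g$ordinal <- i; g
    }))
  } else if (reason == 3) {
    if (n != 1) stop("reason 3 needs a single-lesion report")
    type <- report$lesions$Primary_tumour[1]
    surface <- .gen_tumours$surface[match(type, .gen_tumours$preferred)]
    report$diagnosis_section <- sample(
      c(sprintf("No definitive features; %s not excluded.", surface),
        sprintf("Cannot exclude a %s.", surface)), 1)
    report$lesions <- report$lesions[0, , drop = FALSE]
  } else if (reason == 4) {
    if (n < 1) stop("reason 4 needs at least one lesion")
    p <- .reason4_pairs[sample(nrow(.reason4_pairs), 1), ]
    report$diagnosis_section <- paste0(p$written, ".")
    report$lesions <- gold1(p$gold)
  } else {
    if (n < 1) stop("reason 5 needs at least one lesion")
    p <- .reason5_pairs[sample(nrow(.reason5_pairs), 1), ]
    report$diagnosis_section <- paste0(p$written, ".")
    report$lesions <- gold1(p$gold)
  }
  report$injected_reason <- as.integer(reason)
  report$report_text <- .assemble_sections(report$assay_type,
                                           report$diagnosis_section,
                                           report$with_prognosis,
                                           report$joiner)
  report
}

#' Generate a synthetic corpus with gold tables
#'
#' Draws a misdiagnosis reason (or none) per report at the configured rates,
#' generates every report deterministically, and lays the corpus out in the
#' lab-export row format consumed by [read_lab_export()] /
#' [concatenate_submissions()], splitting a configurable fraction of
#' submissions over several consecutive rows.
#'
#' @param spec A `ptr_corpus_spec`.
#' @return A list of class `ptr_gold_corpus` with elements `spec`, `export`
#'   (a `ptr_lab_export`-shaped data frame), `gold_reports` (one row per
#'   report: `report_ref`, `assay_type`, `lab_dialect`, `n_gold_tumours`,
#'   `injected_reason`, `report_text`), `gold_tumours` (one row per gold
#'   tumour in registry-form fields) and `reports` (the report objects).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "ptr_corpus_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.report_seed(spec$seed, 0L, salt = 2))
  reasons <- sample(0:5, spec$n_reports, replace = TRUE,
                    prob = c(1 - sum(spec$failure_rates), spec$failure_rates))
  multirow <- stats::runif(spec$n_reports) < spec$p_multirow
  reports <- lapply(seq_len(spec$n_reports), function(i) {
    generate_report(spec, i,
                    reason = if (reasons[i] > 0) reasons[i] else NA)
  })
  export_rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    frags <- r$report_text
    if (multirow[i]) {
      pieces <- strsplit(r$report_text, "\n", fixed = TRUE)[[1]]
      if (length(pieces) > 1) {
        k <- min(length(pieces), sample(2:3, 1))
        grp <- sort(rep_len(seq_len(k), length(pieces)))
        frags <- vapply(split(pieces, grp), paste, character(1),
                        collapse = "\n")
      }
    }
    data.frame(lab_no = r$lab_no,
               recd = r$recd,
               recd_raw = format(r$recd, "%d/%m/%Y"),
               species = r$species, breed = r$breed, gender = r$gender,
               practice_id = r$practice_id, assay_code = r$assay_code,
               rescomment = unname(frags), stringsAsFactors = FALSE)
  })
  export <- do.call(rbind, export_rows)
  rownames(export) <- NULL
  attr(export, "dialect") <- reports[[1]]$lab_dialect
  class(export) <- c("ptr_lab_export", "data.frame")
  gold_reports <- do.call(rbind, lapply(reports, function(r) {
    data.frame(report_ref = r$lab_no, assay_type = r$assay_type,
               lab_dialect = r$lab_dialect,
               n_gold_tumours = nrow(r$lesions),
               injected_reason = r$injected_reason,
               report_text = r$report_text, stringsAsFactors = FALSE)
  }))
  gold_tumours <- do.call(rbind, lapply(reports, function(r) {
    if (nrow(r$lesions) == 0) return(NULL)
    cbind(data.frame(report_ref = r$lab_no, stringsAsFactors = FALSE),
          r$lesions)
  }))
  if (is.null(gold_tumours)) {
    gold_tumours <- data.frame(report_ref = character(0), ordinal = integer(0),
                               Primary_tumour = character(0),
                               stringsAsFactors = FALSE)
  }
  structure(list(spec = spec, export = export, gold_reports = gold_reports,
                 gold_tumours = gold_tumours, reports = reports),
            class = "ptr_gold_corpus")
}

#' Write a corpus to disk in lab-export + gold CSV form
#'
#' @param corpus A `ptr_gold_corpus`.
#' @param dir Output directory (created if needed). Writes `export.csv`
#'   (Table-1-style headers, day-first dates), `gold_reports.csv` and
#'   `gold_tumours.csv`.
#' @return Invisibly `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ex <- corpus$export
  out <- data.frame(LABNO = ex$lab_no, RECD = ex$recd_raw,
                    SPECIES = ex$species, BREED = ex$breed,
                    GENDER = ex$gender, PRACTICE_ID = ex$practice_id,
                    ASSAY_CODE = ex$assay_code, RESCOMMENT1 = ex$rescomment,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, file.path(dir, "export.csv"), row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  utils::write.csv(corpus$gold_reports, file.path(dir, "gold_reports.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  utils::write.csv(corpus$gold_tumours, file.path(dir, "gold_tumours.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(dir)
}
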