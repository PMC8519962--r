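test_that("corpus specification validates its probabilities", {
  expect_s3_class(corpus_spec(n_reports = 10), "ptr_corpus_spec")
  expect_error(corpus_spec(lesion_count_probs = rep(0.2, 6)), "sum to 1")
  expect_error(corpus_spec(failure_rates = c(0.5, 0.6, 0, 0, 0)), "at most 1")
  expect_error(corpus_spec(failure_rates = c(-0.1, 0, 0, 0, 0)))
})

test_that("report generation is deterministic in (seed, index)", {
  spec <- corpus_spec(n_reports = 5, seed = 42)
  r1 <- generate_report(spec, 3)
  r2 <- generate_report(spec, 3)
  expect_identical(r1$report_text, r2$report_text)
  expect_identical(r1$lesions, r2$lesions)
  r_other <- generate_report(spec, 4)
  expect_false(identical(r1$report_text, r_other$report_text))
  co1 <- generate_corpus(corpus_spec(n_reports = 20, seed = 8))
  co2 <- generate_corpus(corpus_spec(n_reports = 20, seed = 8))
  expect_identical(co1$export, co2$export)
  expect_identical(co1$gold_tumours, co2$gold_tumours)
})

test_that("multi-lesion reports use the delimiter layout of the template", {
  spec <- corpus_spec(n_reports = 1, seed = 1,
                      lesion_count_probs = c(0, 0, 0, 1, 0, 0))
  r <- generate_report(spec, 1)
  expect_equal(nrow(r$lesions), 4)
  style <- detect_delimiter_style(r$diagnosis_section)
  expect_true(style %in% c("numeric", "alphabetic"))
  if (style == "numeric") {
    expect_match(r$diagnosis_section, "^1\\. ")
    expect_match(r$diagnosis_section, "\n4\\. ")
  }
})

test_that("generator output parses through ingest with zero warnings", {
  spec <- corpus_spec(n_reports = 40, seed = 13)
  co <- generate_corpus(spec)
  expect_no_warning(recs <- concatenate_submissions(co$export, the_dialects))
  expect_equal(nrow(recs), 40)
  expect_no_warning(filter_species(recs))
  # and survives a disk round trip in the lab-export format
  dir <- withr::local_tempdir()
  write_corpus(co, dir)
  rows <- read_lab_export(file.path(dir, "export.csv"),
                          dialect = co$reports[[1]]$lab_dialect)
  expect_no_warning(recs2 <- concatenate_submissions(rows, the_dialects,
                                                     dialect = attr(co$export, "dialect")))
  expect_identical(recs2$report_text, recs$report_text)
})

test_that("clean corpora round-trip: pipeline output equals gold exactly", {
  for (seed in c(2, 29)) {
    co <- generate_corpus(corpus_spec(n_reports = 80, seed = seed))
    reg <- build_registry(co$export)
    res <- score_corpus(reg, co)
    expect_equal(res$groups$accuracy[res$groups$stratum == "overall"], 1)
    # field-level equality, not only type multisets
    cols <- c("Primary_tumour", "Grade_2_tier", "Grade_3_tier",
              "Differentiation", "Location", "Uncertainty_terms")
    pred <- reg[, c("ReportRef", cols)]
    gold <- co$gold_tumours
    gold <- data.frame(ReportRef = gold$report_ref, gold[, cols],
                       stringsAsFactors = FALSE)
    rownames(pred) <- rownames(gold) <- NULL
    expect_equal(pred, gold, ignore_attr = TRUE)
  }
})

test_that("failure injection rewrites text and gold per mechanism", {
  spec <- corpus_spec(n_reports = 1, seed = 5)
  base1 <- generate_report(spec, 1, reason = 1)
  expect_equal(base1$assay_type, "cytology")
  expect_false(grepl("lipoma", tolower(base1$diagnosis_section)))
  expect_equal(base1$lesions$Primary_tumour, "Lipoma")

  base2 <- generate_report(spec, 2, reason = 2)
  expect_gte(nrow(base2$lesions), 2)
  expect_equal(detect_delimiter_style(base2$diagnosis_section), "none")
  expect_equal(length(unique(base2$lesions$Primary_tumour)), 1)

  base3 <- generate_report(spec, 3, reason = 3)
  expect_equal(nrow(base3$lesions), 0)
  expect_match(tolower(base3$report_text), "not excluded|cannot exclude")

  base4 <- generate_report(spec, 4, reason = 4)
  expect_equal(nrow(base4$lesions), 1)
  base5 <- generate_report(spec, 5, reason = 5)
  expect_true(base5$lesions$Primary_tumour %in%
                c("Soft tissue sarcoma", "Thyroid carcinoma"))

  # inapplicable mechanisms are an error
  single <- generate_report(corpus_spec(
    n_reports = 1, seed = 9, lesion_count_probs = c(1, 0, 0, 0, 0, 0)), 1)
  expect_error(inject_failure(single, 2), "two lesions")
  expect_error(inject_failure(single, 1), "lipoma")
})

test_that("the default pipeline errs exactly as each mechanism intends", {
  spec <- corpus_spec(n_reports = 5, seed = 21)
  for (reason in 1:5) {
    r <- generate_report(spec, reason, reason = reason)
    rows <- make_lab_rows(r$lab_no, r$report_text, species = r$species,
                          assay_code = r$assay_code)
    attr(rows, "dialect") <- r$lab_dialect
    reg <- build_registry(rows)
    pred <- sort(reg$Primary_tumour)
    gold <- sort(r$lesions$Primary_tumour)
    expect_false(identical(pred, gold),
                 label = paste("reason", reason, "should misdiagnose"))
    if (reason == 2) expect_equal(length(pred), 1)
    if (reason == 3) expect_gte(length(pred), 1)
  }
})

test_that("failure assignment follows the configured rates in expectation", {
  rates <- c(6, 7, 6, 2, 2) / 400
  co <- generate_corpus(corpus_spec(n_reports = 400, seed = 17,
                                    failure_rates = rates))
  injected <- co$gold_reports$injected_reason
  expect_true(sum(!is.na(injected)) > 5 && sum(!is.na(injected)) < 50)
  # mutually exclusive per report: one reason recorded at most
  expect_true(all(is.na(injected) | injected %in% 1:5))
})
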