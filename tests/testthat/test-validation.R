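mk_gold <- function(refs_types, assay = "cytology", text = "DIAGNOSIS x",
                    reason = NA_integer_) {
  gr <- data.frame(report_ref = names(refs_types),
                   assay_type = rep_len(assay, length(refs_types)),
                   lab_dialect = "lab_a",
                   n_gold_tumours = lengths(refs_types),
                   injected_reason = rep_len(reason, length(refs_types)),
                   report_text = rep_len(text, length(refs_types)),
                   stringsAsFactors = FALSE)
  gt <- do.call(rbind, lapply(names(refs_types), function(r) {
    tt <- refs_types[[r]]
    if (length(tt) == 0) return(NULL)
    data.frame(report_ref = r, ordinal = seq_along(tt), Primary_tumour = tt,
               stringsAsFactors = FALSE)
  }))
  if (is.null(gt)) {
    gt <- data.frame(report_ref = character(0), ordinal = integer(0),
                     Primary_tumour = character(0), stringsAsFactors = FALSE)
  }
  list(gold_reports = gr, gold_tumours = gt)
}

mk_pred <- function(refs_types) {
  rows <- do.call(rbind, lapply(names(refs_types), function(r) {
    tt <- refs_types[[r]]
    if (length(tt) == 0) return(NULL)
    data.frame(ReportRef = r, Primary_tumour = tt, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(ReportRef = character(0),
                       Primary_tumour = character(0), stringsAsFactors = FALSE)
  }
  rows
}

test_that("perfect predictions score 100% in every stratum", {
  gold <- mk_gold(list(A = "Lipoma", B = c("Lipoma", "Lymphoma")))
  res <- score_corpus(mk_pred(list(A = "Lipoma", B = c("Lipoma", "Lymphoma"))),
                      gold)
  expect_true(all(res$groups$accuracy == 1))
  expect_equal(nrow(res$errors), 0)
  expect_equal(res$lesion_f1, 1)
})

test_that("success is a report-level multiset comparison", {
  gold <- mk_gold(list(A = c("Lipoma", "Lipoma"), B = "Lymphoma"))
  # order must not matter, multiplicity must
  res <- score_corpus(mk_pred(list(A = c("Lipoma", "Lipoma"),
                                   B = "Lymphoma")), gold)
  expect_equal(res$groups$accuracy[res$groups$stratum == "overall"], 1)
  res2 <- score_corpus(mk_pred(list(A = "Lipoma", B = "Lymphoma")), gold)
  expect_equal(res2$groups$matched[res2$groups$stratum == "overall"], 1)
  expect_equal(res2$errors$report_ref, "A")
})

test_that("stratified accuracies reproduce the published arithmetic", {
  # 298 single-lesion reports with 12 errors -> 96.0%; 102 multi with 11 -> 89%
  singles <- setNames(rep(list("Lipoma"), 298), sprintf("S%03d", 1:298))
  multis <- setNames(rep(list(c("Lipoma", "Lymphoma")), 102),
                     sprintf("M%03d", 1:102))
  gold <- mk_gold(c(singles, multis))
  pred <- c(singles, multis)
  for (i in 1:12) pred[[i]] <- "Seminoma"
  for (i in 299:309) pred[[i]] <- "Seminoma"
  res <- score_corpus(mk_pred(pred), gold)
  g <- res$groups
  expect_equal(g$matched[g$stratum == "single"], 286)
  expect_equal(round(100 * g$accuracy[g$stratum == "single"]), 96)
  expect_equal(g$matched[g$stratum == "multiple"], 91)
  expect_equal(round(100 * g$accuracy[g$stratum == "multiple"]), 89)
  # exact binomial interval brackets the point estimate
  expect_true(all(g$ci_low <= g$accuracy & g$accuracy <= g$ci_high))
})

test_that("scoring is invariant under report reordering", {
  gold <- mk_gold(list(A = "Lipoma", B = "Lymphoma", C = "Seminoma"))
  pred <- mk_pred(list(A = "Lipoma", B = "Seminoma", C = "Seminoma"))
  res1 <- score_corpus(pred, gold)
  res2 <- score_corpus(pred[rev(seq_len(nrow(pred))), ], gold)
  expect_equal(res1$groups, res2$groups)
})

test_that("predictions for unknown reports are a hard error", {
  gold <- mk_gold(list(A = "Lipoma"))
  expect_error(score_corpus(mk_pred(list(Z = "Lipoma")), gold), "Z")
})

test_that("error classification follows the five-reason rules", {
  expect_equal(classify_error(character(0), "Lipoma",
                              "CYTOLOGICAL INTERPRETATION Aspiration of adipose tissue."),
               1L)
  expect_equal(classify_error("Lipoma", c("Lipoma", "Lipoma", "Lipoma"),
                              "DIAGNOSIS All 3 sites: Lipoma. PROGNOSIS Good"),
               2L)
  expect_equal(classify_error("Lymphoma", character(0),
                              "DIAGNOSIS Lymphoma not excluded. PROGNOSIS x"),
               3L)
  expect_equal(classify_error("Hepatoid carcinoma", "Anal sac carcinoma",
                              "DIAGNOSIS Hepatoid (perianal) carcinoma."),
               4L)
  expect_equal(classify_error("Mesenchymal neoplasia", "Soft tissue sarcoma",
                              "DIAGNOSIS Mesenchymal neoplasia."),
               5L)
  expect_true(is.na(classify_error("Lipoma", "Lymphoma",
                                   "DIAGNOSIS Lipoma.")))
  # a delimited multi-tumour miss is not reason 2
  expect_true(is.na(classify_error("Lipoma", c("Lipoma", "Lymphoma"),
                                   "DIAGNOSIS 1. Lipoma 2. Lymphoma")))
})

test_that("reason-k-only corpora classify every error as reason k", {
  for (k in 1:5) {
    rates <- rep(0, 5)
    rates[k] <- 0.25
    co <- generate_corpus(corpus_spec(n_reports = 60, seed = 30 + k,
                                      failure_rates = rates))
    reg <- build_registry(co$export)
    res <- score_corpus(reg, co)
    expect_gt(nrow(res$errors), 0)
    expect_true(all(res$errors$assigned_reason == k),
                label = paste("reason", k))
    expect_true(all(res$errors$injected_reason == k))
  }
})

test_that("accuracy on corrupted corpora recovers one minus the rate", {
  rates <- c(6, 7, 6, 2, 2) / 400
  accs <- vapply(1:6, function(s) {
    co <- generate_corpus(corpus_spec(n_reports = 400, seed = 100 + s,
                                      failure_rates = rates))
    reg <- build_registry(co$export)
    res <- score_corpus(reg, co)
    res$groups$accuracy[res$groups$stratum == "overall"]
  }, numeric(1))
  expected <- 1 - sum(rates)
  ci <- stats::binom.test(377, 400)$conf.int
  expect_gte(mean(accs), ci[1])
  expect_lte(mean(accs), ci[2])
})
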