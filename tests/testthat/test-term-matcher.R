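test_that("first_match honours lexicon order, not text position", {
  unc <- the_lexicons$uncertainty
  expect_equal(first_match("Consistent with MCT (second grade), forelimb",
                           unc), "Consistent with")
  pt <- the_lexicons$primary_tumour
  expect_equal(first_match("Malignant mixed mammary gland tumour", pt),
               "Mixed mammary gland tumour")
  expect_true(is.na(first_match("", pt)))
  expect_true(is.na(first_match("nothing relevant", pt)))
  # "Highly likely" outranks the generic capture term "Likely"
  expect_equal(first_match("lymphoma highly likely", unc), "Highly likely")
})

test_that("prepending a more specific matching entry changes the result", {
  set.seed(5)
  for (i in 1:25) {
    generic <- random_word(1, 3, 5)
    specific <- paste0(random_word(1, 3, 5), " ", generic)
    lex <- structure(
      data.frame(surface = generic, excluded = FALSE,
                 maps_to = NA_character_, stringsAsFactors = FALSE),
      class = c("ptr_lexicon", "data.frame"))
    text <- paste("x", specific, "y")
    expect_equal(first_match(text, lex), generic)
    lex2 <- lex
    lex2 <- rbind(data.frame(surface = specific, excluded = FALSE,
                             maps_to = NA_character_,
                             stringsAsFactors = FALSE), lex)
    class(lex2) <- class(lex)
    expect_equal(first_match(text, lex2), specific)
  }
})

test_that("first_match agrees with a brute-force oracle", {
  set.seed(303)
  for (i in 1:300) {
    text <- paste(sample(c(letters[1:5], " "), sample(4:30, 1),
                         replace = TRUE), collapse = "")
    surfaces <- unique(vapply(seq_len(sample(2:6, 1)), function(j) {
      paste(sample(letters[1:5], sample(1:3, 1), replace = TRUE),
            collapse = "")
    }, character(1)))
    lex <- structure(
      data.frame(surface = surfaces, excluded = FALSE,
                 maps_to = NA_character_, stringsAsFactors = FALSE),
      class = c("ptr_lexicon", "data.frame"))
    expect_identical(first_match(text, lex), oracle_first_match(text, lex),
                     label = paste("text:", text))
  }
})

test_that("annotate_lesion reproduces the worked-example rows", {
  cand <- extract_location_candidates(fixture_report_text(), kw_histo)
  a3 <- annotate_lesion("Consistent with MCT (second grade), forelimb",
                        cand, the_lexicons)
  expect_equal(a3$primary_tumour, "MCT")
  expect_equal(a3$grade_3_tier, "second grade")
  expect_equal(a3$uncertainty, "Consistent with")
  expect_equal(a3$location, "Forelimb")
  expect_equal(a3$location_source_rank, 1L)
  a4 <- annotate_lesion("Low-grade cutaneous Lymphoma, highly likely",
                        cand, the_lexicons)
  expect_equal(a4$primary_tumour, "Lymphoma")
  expect_equal(a4$grade_2_tier, "Low-grade")
  expect_equal(a4$uncertainty, "Highly likely")
  expect_equal(a4$location, "cutaneous")
  a0 <- annotate_lesion("Osteosarcoma", NULL, the_lexicons)
  expect_equal(a0$primary_tumour, "Osteosarcoma")
  expect_true(all(is.na(unlist(
    a0[c("grade_2_tier", "grade_3_tier", "differentiation", "uncertainty",
         "location")]))))
})

test_that("location falls back through ranked section sources", {
  cand <- data.frame(rank = c(2L, 3L),
                     text = c("mass removed from the forelimb",
                              "section of spleen examined"),
                     stringsAsFactors = FALSE)
  a <- annotate_lesion("Lipoma with no site given", cand, the_lexicons)
  expect_equal(a$location, "Forelimb")
  expect_equal(a$location_source_rank, 2L)
  a3 <- annotate_lesion("Lipoma", cand[cand$rank == 3, ], the_lexicons)
  expect_equal(a3$location, "Spleen")
  expect_equal(a3$location_source_rank, 3L)
})

test_that("every matched field is an exact member of its lexicon", {
  lesions <- c("Consistent with MCT (second grade), forelimb",
               "Low-grade cutaneous Lymphoma, highly likely",
               "Malignant mixed mammary gland tumour, gland three")
  for (l in lesions) {
    a <- annotate_lesion(l, NULL, the_lexicons)
    for (cat in c("primary_tumour", "grade_2_tier", "grade_3_tier",
                  "differentiation", "uncertainty", "location")) {
      v <- a[[cat]]
      if (!is.na(v)) expect_true(v %in% the_lexicons[[cat]]$surface)
    }
  }
})

test_that("excluded lexicon entries are not registrable tumours", {
  ok <- annotate_lesion("Lipoma", NULL, the_lexicons)
  expect_true(is_registrable_tumour(ok, the_lexicons$primary_tumour))
  bad <- annotate_lesion("follicular cyst on the neck", NULL, the_lexicons)
  expect_equal(bad$primary_tumour, "follicular cyst")
  expect_false(is_registrable_tumour(bad, the_lexicons$primary_tumour))
  none <- annotate_lesion("inflammatory change only", NULL, the_lexicons)
  expect_false(is_registrable_tumour(none, the_lexicons$primary_tumour))
})

test_that("unmatched sampling is seeded, capped and reproducible", {
  ann <- data.frame(text = paste0("t", 1:500),
                    primary_tumour = NA_character_,
                    stringsAsFactors = FALSE)
  s1 <- sample_unmatched(ann, "primary_tumour", n = 200, seed = 9)
  s2 <- sample_unmatched(ann, "primary_tumour", n = 200, seed = 9)
  expect_length(s1, 200)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, sample_unmatched(ann, "primary_tumour", n = 200, seed = 10)))
  small <- ann[1:50, ]
  expect_length(sample_unmatched(small, "primary_tumour", n = 200, seed = 1),
                50)
  matched <- ann
  matched$primary_tumour <- "Lipoma"
  expect_length(sample_unmatched(matched, "primary_tumour", n = 10, seed = 1),
                0)
})
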