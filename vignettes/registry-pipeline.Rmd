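---
title: "Building a pathology-based tumour registry from free-text reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a pathology-based tumour registry from free-text reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Veterinary diagnostic laboratories report tumour diagnoses as free text:
a submission carries animal metadata (species, breed, sex and neuter
status, submitting practice) plus a narrative pathology report with
sections such as DIAGNOSIS, PROGNOSIS, CLINICAL HISTORY and HISTOLOGY
(cytology reports open their diagnosis with CYTOLOGICAL INTERPRETATION).
A pathology-based tumour registry (PTR) turns a stream of such electronic
pathology records (EPRs) into a flat, queryable table: one row per tumour,
with the diagnosis, grading, differentiation, anatomical location,
hedging ("uncertainty") terms and the animal's details normalized to
preferred vocabularies.

`ptrminer` implements that construction as a deliberately simple,
fully rule-based pipeline — ordered dictionary lookup rather than machine
learning — because the registry's value rests on the method being
auditable: every extracted value can be traced to a keyword position and a
lexicon line.

## The pipeline

1. **Ingest** (`read_lab_export()`, `concatenate_submissions()`,
   `filter_species()`). Some laboratories deliver one submission as a run
   of consecutive rows sharing a sample reference; fragments are joined in
   order with a newline. Grouping is by *runs* of equal reference — a
   reference that reappears later is a new submission (a warning is
   emitted), because the feed format only guarantees adjacency. Only dogs
   and cats are kept; the filter is pure and logs its discards.

2. **Section extraction** (`extract_diagnosis_section()`,
   `extract_location_candidates()`). Keywords are located by
   case-insensitive substring search with first-position semantics and no
   word-boundary anchoring, mirroring the spreadsheet SEARCH mechanism the
   registry was originally built with; that choice is a documented source
   of false keyword hits and is measurable with the validation module.
   The diagnosis span runs from the diagnosis keyword to the first of
   PROGNOSIS or CLINICAL HISTORY (prognosis sections are sometimes
   omitted). Lesion-location text can live in three places, consulted in
   priority order: next to the diagnosis (rank 1), between CLINICAL
   HISTORY and HISTOLOGY (rank 2), and between HISTOLOGY and COMMENTS
   (rank 3). HTML remnants (`<br>`, `&nbsp;`, stray angle brackets) are
   collapsed to single spaces first; all spans refer to the cleaned text,
   so only the relative order of keyword positions — not the original
   absolute offsets — is preserved.

3. **Lesion separation** (`split_lesions()`). Multiple lesions are almost
   always written as numbered ("1."–"6.") or lettered ("A"–"F") items.
   Only those markers are searched, which caps a report at six tumours by
   construction; anything after a seventh marker stays attached to lesion
   six. Numeric markers require the trailing dot so that "grade 2" is
   never a delimiter; alphabetic markers must be standalone tokens
   (optionally followed by "." or ")"), since the sources only state the
   marker alphabet, not its context. Undelimited multi-tumour phrasings
   ("Seminoma in both testicles") are *deliberately not recovered*: they
   are a documented failure mode (reason 2 below) that the pipeline must
   reproduce, not fix.

4. **Classifier matching** (`first_match()`, `annotate_lesion()`). Six
   ordered lexicons — tumour type, a two-tier grade (Kiupel for mast cell
   tumours), a three-tier grade (Patnaik), differentiation, uncertainty
   terms, and location — are applied to each lesion. Matching is
   first-match *by lexicon order*, not longest-match: specificity is
   enforced by curators placing specific phrases above generic "capture
   terms" ("Mixed mammary gland tumour" above "Tumour"). Only a single
   match per category is recorded. Location tries the lesion text first,
   then the rank-2 and rank-3 spans. Lesions whose tumour-type match is
   flagged `excluded` (hamartomas, cysts, tumour-like masses) or that
   match nothing are not registrable; a report with no registrable lesion
   contributes no rows. `sample_unmatched()` supports the iterative
   curation loop (seeded batches of 200 unmatched texts for review).

5. **Normalization** (`normalize_term()`, `normalize_breed()`,
   `parse_gender()`). Surface forms map to preferred terms by exact
   case-folded lookup; unmapped surfaces pass through *visibly* rather
   than being silently bucketed, which is what keeps the curation loop
   honest. Grades collapse across numbering styles ("grade II", "second
   grade" → "grade 2", stored as the numeral "2"); dog breeds follow
   FCI/AKC names and cat breeds FIFE/TICA, with popular hybrids kept as-is.
   Every map is idempotent (preferred terms are fixed points).

6. **Registry assembly** (`assign_tumour_refs()`,
   `merge_animal_tumour()`, `write_registry()`). Tumours get references
   `R.x-T.n` with contiguous ordinals; animal and tumour tables join on
   the report reference into exactly 15 columns (A–O), with ISO dates and
   opaque practice identifiers (no geography is ever computed). Output is
   RFC-4180 CSV or JSON-lines, bit-stable and round-trippable.

## Aggregation of rare types

The published registry keeps a tumour type as its own category only when
it appears at least 10 times, routing rarer or generically-described
types into six catch-all categories (Carcinoma_others, Adenoma_others,
Epithelioma_others, Epithelial tumour_others,
Mesenchymal_neoplasias_others, Neoplasia_Tumours_others) and folding
plasmacytomas and myelomas into "Plasma cell tumour". That threshold is a
property of a large corpus, not of a single report, so `ptrminer`
implements it as an explicit post-pass (`apply_aggregation()`, default
threshold 10) that is **off** in `build_registry()` by default: on
desk-scale corpora of a few hundred reports nearly every type would fall
under the threshold and the round-trip guarantee of the synthetic
harness (below) would be meaningless. Users reconstructing a large
registry should run the post-pass deliberately.

## The synthetic corpus and what it does (not) show

Real EPRs are access-restricted, so `generate_corpus()` builds corpora
with known gold annotations. Its defaults are the study conditions of the
registry it emulates: 8.4% of reports feline, 36.6% cytology, and a
per-report lesion-count distribution (87.8% single-lesion, median 1)
derived from the published per-tumour counts. The generation vocabulary
is a closed world drawn from the bundled lexicons, so on a *clean* corpus
a correct pipeline recovers every gold field exactly — any miss is a
pipeline bug, not a data gap. Reports are deterministic in
`(seed, index)`; a fraction (default 30%) is emitted as multi-row
submissions to exercise concatenation.

Five misdiagnosis mechanisms, mirroring the error taxonomy observed in
the published expert review (23 errors in 400 reports, split 6/7/6/2/2),
can be injected at configurable, mutually-exclusive per-report rates:

1. a lipoma reported as "aspiration of adipose tissue" without the word
   *lipoma* (gold: lipoma; pipeline finds nothing);
2. multiple tumours written without delimiters ("All 4 sites: Lipoma";
   gold keeps all, pipeline finds one);
3. a hedged differential ("Lymphoma not excluded"; gold: non-tumour,
   pipeline promotes the hedged diagnosis);
4. a location-confused diagnosis (hepatoid vs anal sac carcinoma);
5. a generic ancestor written for a specific type (mesenchymal neoplasia
   for soft tissue sarcoma).

Gold always carries the *expert* answer, so the default pipeline is
expected to err on injected reports — the harness validates that the
pipeline errs for the right reasons.

What passing these tests does **not** show: robustness to real
laboratories' full phrase diversity (the bundled lexicons are a reduced
set of a few hundred entries; the production lexicon had 1808 tumour
types), to spelling errors, to decimal measurements that can collide with
numeric markers, or to section keyword inventories beyond the bundled
dialect examples (the two bundled dialects differ in markup habits and
assay codes but share most keywords, since fuller per-laboratory
inventories are not published).

## Validation

`score_corpus()` scores at report level: a report is a success when the
multiset of predicted tumour types equals the gold multiset after
normalization — matching the whole-report expert review protocol; a
per-lesion multiset F1 is also reported as a convenience metric that is
*not* part of that protocol. Results are stratified by gold tumour count
(single vs multiple) crossed with assay type, with exact binomial 95%
confidence intervals (an artifact addition; the original protocol
reported point accuracies only). Gold non-tumour reports (reason 3) are
stratified into the single group, as their gold count is below two.
`classify_error()` assigns each miss to reasons 1–5 by ordered rules;
reason 4 uses an explicit location-confusion pair table and reason 5 an
explicit generic-to-specific (is-a) table shipped with the lexicons,
because under type-level scoring those are the forms in which location
and generalization errors actually surface.

## Numerical and design choices

- Character indexing is 1-based with half-open spans; first occurrence
  wins for every keyword; ties cannot arise.
- "CLINICAL DIAGNOSIS" is accepted as a synonym boundary alongside
  "CLINICAL HISTORY" — the source descriptions use both and never
  disambiguate.
- Dates parse day-first with a two-digit-year pivot at 2000; the registry
  emits ISO-8601 regardless of input dialect. `ResultDate` is the
  sample-received date, the only date present in the export.
- Missing species is a discard (logged), not an error.
- The seeded helpers (`sample_unmatched()`, the generator) save and
  restore the caller's RNG state.
- Test and validation problem sizes — corpora of 400–1000 reports, 50
  replicate corpora for rate recovery, 10,000 randomized instances for
  the oracle-equivalence checks — were chosen to put binomial sampling
  error well inside the margins being asserted.

## A worked run

```r
library(ptrminer)

fixture <- system.file("extdata", "table1_export.csv", package = "ptrminer")
reg <- build_registry(fixture, dialect = "lab_a")
reg[, c("TumourRef", "Primary_tumour", "Grade_3_tier", "Location",
        "Uncertainty_terms")]

co <- generate_corpus(corpus_spec(n_reports = 400, seed = 1,
                                  failure_rates = c(6, 7, 6, 2, 2) / 400))
res <- score_corpus(build_registry(co$export), co)
res
```

## Known limitations

Substring matching without word boundaries can fire inside longer tokens;
lexicon order is the only specificity mechanism; undelimited multi-tumour
reports and hedged differentials are reproduced as errors by design; the
registry has no animal identifier, so repeat sampling of one tumour is
counted repeatedly; and nothing here estimates population denominators —
a pathology-based registry supports proportional descriptions within its
own cohort, not incidence rates.
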