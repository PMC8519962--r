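Package: ptrminer
Title: Rule-Based Tumour Registry Construction from Veterinary Pathology Free Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a pathology-based tumour registry for dogs and cats from
    free-text electronic pathology records. Laboratory exports are ingested and
    concatenated into one record per submission, report sections are located by
    keyword search, the diagnosis section is split into at most six lesions,
    and six ordered look-up tables (tumour type, two grading tiers,
    differentiation, uncertainty terms, location) are applied by first-match
    substring search. Matched surface forms are normalized to preferred terms
    and assembled into a 15-column registry. A synthetic record generator with
    gold annotations and a five-reason misdiagnosis taxonomy supports stratified
    accuracy validation without access to proprietary laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    stringi,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
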