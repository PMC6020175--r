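Package: phimask
Title: Structured-PHI-Guided De-Identification of Clinical Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Masks protected health identifiers (PHI) in free text by fuzzy
    matching against the clean identifiers held in structured administrative
    records. Each PHI token is slid across every character offset of a
    document over a range of window widths; windows whose normalised
    Levenshtein similarity clears a configurable threshold are masked
    in place. The package ships the complete validation framework for the
    approach: a seeded synthetic address-corpus generator, four string
    mutation models (keyboard typos, address-token aliasing, address
    truncation, simulated poor-quality OCR), per-token precision/recall
    scoring, an eight-condition benchmark against published reference
    results, and a partitioned incremental job runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
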