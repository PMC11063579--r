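Package: pseudoreg
Title: Pseudonymization Registry for Multisite Study Subjects and Biosamples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A file-based pseudonymization registry for biomedical research
    networks. Registers study subjects and biosample aliquots, generates
    collision-free pseudonyms with ISO 7064 MOD 37-2 check characters,
    prevents duplicate enrolment through data-quality checks and fuzzy
    record linkage (Jaro-Winkler similarity with blocking), manages visit
    schedules, produces machine-readable biosample labels (DataMatrix, QR,
    Code 128) as self-contained printable HTML sheets, and supports bulk
    CSV import/export with single-writer locking, read-only snapshots,
    audit logging and backup reminders. Ships a deterministic synthetic
    identity generator with ground truth for evaluating linkage quality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stringi,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
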