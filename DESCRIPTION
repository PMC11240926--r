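Package: acpscreen
Title: Sequence-Based Screening of Anticancer Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screening pipeline for anticancer peptides (ACPs) from natural
    sources. Encodes peptide sequences (10-50 residues) into amino acid
    composition, dipeptide composition, k-spaced amino acid pair (CKSAAP)
    and three-state secondary-structure composition features, trains a
    radial-basis-function support vector machine with Platt-scaled
    probabilities, and evaluates it by repeated stratified cross-validation
    (sensitivity, specificity, accuracy, Matthews correlation coefficient,
    ROC/AUC). Includes CD-HIT-style greedy redundancy reduction, two-sample
    differential composition and positional logo statistics, consensus
    voting across external predictors with hypergeometric term enrichment
    of the nominated candidates, and a synthetic peptide generator for
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
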