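Package: pathagree
Title: Reader Agreement Analysis for Digital Pathology Validation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-reader multi-case agreement studies that compare
    digital and optical microscopy for immunohistochemistry biomarker scoring
    (HER2 ordinal 0/1+/2+/3+ and Ki-67 positive/negative, each paired with a
    continuous 0-100 score). Implements ties-corrected Kendall's tau-b with its
    full concordance decomposition, overall and category-specific percent
    correct agreement, disagreement cross-tabulations, deferral and
    cell-sufficiency exclusion rules, averaged pairwise interobserver and
    per-reader intermodality agreement with paired modality differences, and
    percentile bootstrap confidence intervals that resample both readers and
    cases. A latent-trait simulator generates synthetic reader studies with the
    factor structure of whole-slide and tissue-microarray review so the whole
    pipeline is testable without access to any reader-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
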