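Package: svrdecon
Title: Immune Cell Deconvolution of Bulk Expression Profiles by
    nu-Support-Vector Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the relative proportions of immune cell types in bulk
    (mouse) tissue expression profiles by modelling each mixture as a linear
    combination of cell-type-specific reference profiles (Ax = B) and solving
    for the mixing weights with linear-kernel nu-support-vector regression
    over a grid of nu values, keeping the lowest-RMSE fit.  Includes the full
    signature-matrix construction pipeline (one-vs-rest moderated
    differential expression, enrichment-score filtering of non-hematopoietic
    genes, tumor-expressed-gene filtering, and top-n marker selection by
    condition-number minimisation), an in-silico mixture simulator (pure
    profiles, spike-in series, tumor-dilution series) with known ground
    truth, and recovery reports comparing predicted with reference
    compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    e1071,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
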