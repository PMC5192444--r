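Package: structpls
Title: Structured-Output Partial Least Squares for Factorial Metabolomics Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-response partial least squares (PLS2) modelling of omics
    feature tables from multi-factor experimental designs using a structured
    target matrix: declarative Y-block coding that mixes one-of-k categorical
    sub-matrices with ordinal coded columns, crisping of raw predictions back
    to factor levels, block-wise misassignment error sets, replicate-aware
    double cross-validation with averaged confusion matrices and permutation
    p-values, and block-summarised variable importance in projection (VIP)
    scores. Includes a synthetic factorial-design data generator with known
    ground truth, KNN imputation of missing peak areas, and file-based
    reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
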