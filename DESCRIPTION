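Package: sigrevert
Title: Organ-Tropic Expression Signatures and Inverse Connectivity Drug Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives an organ-tropic gene expression signature from
    multi-organ metastatic tumor-cell expression profiles through a
    five-step workflow (per-organ differential expression, nearest
    shrunken centroid marker selection, rank-product and SAM permutation
    validation, hierarchical cluster expansion, and down-gene appending),
    maps the signature to microarray probe tag sets, and ranks
    drug-perturbation instances by a Kolmogorov-Smirnov connectivity
    score to nominate signature-reverting compounds. Includes a
    synthetic-data module that emulates the multi-organ replicate design
    and a rank-matrix perturbation database with planted inverter and
    mimic compounds, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    matrixStats,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
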