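Package: doublehit
Title: Pharmacogenomic Secondary-Drug Ranking with a Single-Cell Double-Hit Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for data-driven drug repurposing against
    drug-resistant cancer cell populations. Classifies cell lines as sensitive
    or resistant to a primary drug from a drug-by-cell-line IC50 panel using an
    empirical quantile threshold, and ranks candidate secondary drugs
    ("secDrugs") by the number of resistant lines they kill. Fits
    variable-slope sigmoidal (four-parameter logistic) dose-response curves,
    quantifies drug synergy with the Chou-Talalay median-effect combination
    index, dose-reduction index and isobologram coordinates, scores
    marker-gene programs (EMT, stemness, target pathways) per single-cell
    subclone to form a combined "double-hit" score, detects
    treatment-induced cluster erosion with Fisher exact tests, and
    reverse-matches treatment-induced differential-expression signatures
    against patient recurrence signatures. Seeded synthetic-data generators
    with ground-truth manifests support end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
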