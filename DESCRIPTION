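Package: pharmacospace
Title: Drug Response Prediction from Bulk and Single-Cell Transcriptomes via a
    Latent Pharmacogenomic Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a low-dimensional pharmacogenomic space from cell-line drug
    screening panels using a calibrated matrix-factorization recommender that
    down-weights extrapolated IC50 values, and projects unseen bulk or
    single-cell transcriptomic profiles into that space to predict drug
    sensitivity. Clone-level predictions are aggregated into tumor-level
    dose-response values with a Newton root-finder on the mixture sigmoid,
    intra-tumor transcriptomic heterogeneity is scored as the entropy of
    cell-type or cluster compositions, and drug combinations are prioritized
    under an independent-action model. Includes seeded synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
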