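Package: ptsscore
Title: Peri-Tumoral Stroma Scoring from Histology Label Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the peri-tumoral stroma (PTS) score of colon-cancer
    histology: seven-class tissue segmentation of H&E tiles with a compact
    U-Net trained in R, Macenko stain normalization and per-channel histogram
    normalization, morphological closing of the tumor mask to delineate the
    tumor region, the PTS score as stroma area within that region divided by
    tumor area, and the cohort statistics relating the score to lymph-node
    metastasis (descriptive tables, univariate logistic odds ratios with Wald
    intervals, rank-sum ROC AUC with DeLong intervals, T-stage subgroups).
    Includes synthetic-data generators (labeled tiles, whole-slide label maps
    with analytically known scores, cohorts with configurable logit effects)
    so the full pipeline is testable end to end without external images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
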