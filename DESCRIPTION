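Package: charmark
Title: Character-Level Markov Chain Biomarkers from Speech Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models transcribed speech as character-level Markov chains over a
    27-symbol alphabet (a-z plus space), extracts Laplace-smoothed
    steady-state character distributions as interpretable linguistic
    features, and validates them as candidate digital biomarkers of
    cognitive decline: two-sample Kolmogorov-Smirnov screening with
    Bonferroni correction, k-means/PCA structure discovery, and
    L1-penalised logistic regression under participant-grouped stratified
    cross-validation with calibration and threshold analysis. Includes a
    seeded synthetic-transcript generator so the full pipeline is testable
    without access-gated clinical corpora, and exporters for transition
    networks and feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    pROC,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
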