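Package: immunosig
Title: Immune Signature Scoring and Genomic Correlates of Immunotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Trains a transcriptional immune-signature predictor of
    immunotherapy response (differential gene selection followed by a
    Bayesian compound covariate predictor yielding a per-sample IS score),
    computes a chromosomal-instability (CIN) score from gene-level GISTIC2
    copy-number values, classifies tumors into mutator (M), chromosome-
    instable (C) and NOS genomic types, and runs the downstream association
    scans (Wilcoxon with Benjamini-Hochberg FDR control, per-cancer logistic
    odds ratios, regressions) and survival analyses (Kaplan-Meier, log-rank,
    Cox). Ships a synthetic cohort generator with planted differential
    expression, mutation burden, copy-number magnitude and survival hazard
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
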