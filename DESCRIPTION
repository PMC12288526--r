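Package: trialhist
Title: Trial-History Coding Analyses for Freely Moving Perceptual Decision Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for studying how previous choices and outcomes
    (trial history) shape behavior and cortical population activity in a
    self-initiated, freely moving evidence-accumulation task. Provides a
    synthetic session generator with known ground truth (behavior, tracking,
    and neural populations), a behavioral trial-history logistic GLM and
    psychometric fits with lapse rates, balanced one-versus-all population
    decoders with confusion and cross-temporal generalization analyses, a
    kernel-based linear encoding model with ridge regression and maximal
    versus unique explained-variance partitioning against movement
    regressors, and PCA/Procrustes comparison of encoding-weight geometry
    across sessions and subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
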