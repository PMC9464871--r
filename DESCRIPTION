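Package: noisytile
Title: Noisy Label Ensembles for Selective Tile Classification in Computational Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how deliberate label noise affects the
    robustness and transferability of bagging classifier ensembles on
    histopathology image tiles. Provides a synthetic multi-site,
    quality-graded tile cohort generator with controllable image
    degradations (blur, contrast, brightness, stain gain, JPEG
    compression); patient-level repeat, member, and site-restricted data
    splitting; per-patient single-class selection with exact-fraction
    label flipping; training of odd-sized member ensembles with
    best-epoch checkpointing and majority-vote aggregation; selective
    prediction by ensemble-agreement thresholds with accuracy/retention
    curves, false-positive/false-negative tracking, and suspect-label
    flagging; and one-way ANOVA with Holm-corrected pairwise post-hoc
    t-tests for group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
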