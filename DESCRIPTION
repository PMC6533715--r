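Package: esitools
Title: Emphysema Severity Scoring from the Shape of the Flow-Volume Curve
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the Emphysema Severity Index (ESI), a 0-10 score derived
    solely from the shape of the descending limb of the maximal expiratory
    flow-volume (MEFV) curve, by fitting a two-regime biomechanical power-law
    model. Also provides paired inspiratory/expiratory CT densitometry
    (%LAA metrics, parametric response mapping, NE/ME/SE staging), an
    ordered-category dissimilarity (SILA) with affinity-propagation clustering
    of parenchymal pattern profiles, a seeded synthetic COPD cohort generator,
    and the validation statistics used to benchmark the score (Welch ANOVA,
    Games-Howell post-hocs, Steiger's Z for dependent correlations,
    cross-validated logistic ROC analysis).
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
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
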