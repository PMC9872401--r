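Package: metabomr
Title: Two-Stage Metabolome-Wide and Phenome-Wide Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization screens of blood
    metabolites against a disease outcome, followed by a phenome-wide scan of
    identified metabolites across a phenotype catalog with effects rescaled to
    a fixed percentage reduction in primary-outcome risk. Implements summary-
    statistics reading and allele harmonization with proxy substitution, greedy
    LD clumping and instrument-strength quality control, the inverse-variance-
    weighted estimator with Cochran's Q model selection, weighted-median,
    MR-Egger and robust adjusted profile score (RAPS) estimators, Bonferroni
    multiplicity control at both stages, and a synthetic GWAS summary-statistics
    generator with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
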