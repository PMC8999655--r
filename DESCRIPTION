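Package: ybrca1
Title: Validation and Majority-Voting Integration of Yeast-Based BRCA1
    Functional Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and performance evaluation of yeast-based functional
    assays for BRCA1 missense variants (intra- and inter-chromosomal homologous
    recombination, gene reversion, and small colony phenotype readouts), and
    integration of the per-assay calls into a single functional classification
    by equal-weight majority voting. Provides per-assay ROC analysis with
    Youden-index best cut-off selection, bootstrap prediction scores for
    per-variant calls, combined-classifier performance statistics (accuracy
    with exact binomial confidence interval, Matthews correlation coefficient,
    Cohen's kappa), a log-normal synthetic replicate generator for testing the
    whole pipeline without wet-lab data, and tidy TSV/CSV interchange for
    replicate-level panels and classification reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
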