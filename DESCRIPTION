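Package: radtiles
Title: CT Radiomics Prediction of Tumor-Infiltrating Lymphocyte Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links CT texture radiomics to tumor-infiltrating lymphocyte (TIL)
    enrichment in solid tumors. Computes an area-weighted TIL enrichment score
    (TILes) from gridded pathology maps with sample-level quality control,
    extracts 88 radiomic features in seven categories (first-order, shape,
    GLCM, GLSZM, CDF, physical, fractal) from masked CT volumes, runs a
    median-split / t-test / alias / VIF / LASSO feature-selection pipeline to
    build a predicted-TILes model, and analyses immunotherapy outcomes
    (Kaplan-Meier, log-rank, Cox, rank and count statistics) by predicted-TILes
    group. Ships a synthetic cohort generator with a controllable
    texture-to-TILes-to-outcome effect chain so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    survival,
    RNifti,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
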