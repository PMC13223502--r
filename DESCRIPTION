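Package: renivim
Title: Renal IVIM and Stretched-Exponential Diffusion Analysis for Early
    Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward models and Levenberg-Marquardt fitters for the
    monoexponential, biexponential (intravoxel incoherent motion, IVIM)
    and stretched-exponential diffusion-MRI signal decay models; the
    MDRD estimated glomerular filtration rate and eGFR-based patient
    grouping; a seeded synthetic cohort generator emulating a three-group
    early chronic kidney disease study (healthy controls, preserved and
    reduced eGFR) with Rician signal noise, two simulated readers and
    semi-quantitative renal pathology scores; and the accompanying
    statistical pipeline: nonparametric group comparison with Dunn post
    hoc tests, Spearman correlation with Bonferroni adjustment, two-way
    random-effects intraclass correlation, and ROC analysis with DeLong
    confidence intervals and Youden-optimal thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
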