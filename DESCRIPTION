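Package: cmrperf
Title: Quantitative Stress Perfusion CMR: Blood Flow, Ischemic Burden and
    Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantitative stress-perfusion cardiac
    magnetic resonance. Estimates myocardial blood flow per segment by
    Fermi-constrained deconvolution of tissue signal-intensity curves
    against a dual-bolus-corrected arterial input function, computes
    myocardial perfusion reserve and mass-weighted ischemic burden on the
    32-sub-segment AHA model, adjudicates a composite cardiovascular
    endpoint with a 90-day revascularization blanking window, and compares
    baseline and perfusion-extended survival risk classifiers with
    cross-validated L1-penalized Cox models, time-dependent ROC/AUC at two
    years, categorical net reclassification improvement and integrated
    discrimination improvement. Includes a synthetic-data module that
    generates dual-bolus perfusion curves, segment maps and survival
    cohorts with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    minpack.lm,
    signal,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
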