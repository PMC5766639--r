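Package: spfmri
Title: Simplified Perfusion Fraction, IVIM and DCE Analysis for Glioma Grading
Version: 0.1.0
Authors@R: person("spfmri", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates microvascular perfusion from three-b-value
    diffusion-weighted MRI via the simplified perfusion fraction (SPF),
    alongside reference intravoxel incoherent motion (IVIM) biexponential
    fitting and extended Tofts pharmacokinetic modelling of dynamic
    contrast-enhanced MRI. Includes hot-spot region-of-interest extraction
    on parametric maps, the complete two-group statistical pipeline used to
    grade gliomas (ICC, Spearman, Mann-Whitney, ROC with Youden thresholds,
    DeLong AUC comparison, leave-one-out cross-validation), and synthetic
    phantom and cohort generators calibrated to published group
    distributions so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
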