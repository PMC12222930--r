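Package: shrubmeta
Title: Meta-Analysis of Shrubland Vegetation Responses to Climate and
    Nitrogen Manipulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for random-effects meta-analysis of
    multi-site shrubland manipulation experiments (warming, altered
    precipitation, drought, nitrogen addition). Computes log
    response-ratio effect sizes and their sampling variances from
    treatment and control arm summaries, pools them within metric by
    treatment strata with DerSimonian-Laird or restricted
    maximum-likelihood heterogeneity estimates, Wald-type z tests and
    bias-corrected bootstrap confidence intervals, screens for
    publication bias with Egger's regression and corrects it with the
    precision-effect estimate with standard error (PEESE), contrasts
    short-term against long-term experiments, and fits mixed-effects
    meta-regressions of driver-standardised sensitivities on site
    climate moderators with AIC-based model selection. Includes a
    synthetic multi-site experiment generator with known truth so every
    stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
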