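Package: lrbayes
Title: Staged Diagnostic Likelihood-Ratio Models for Clinical Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits and evaluates staged probabilistic risk models that combine
    grouped binary and continuous predictors through the odds-ratio form of
    Bayes' rule. Predictors are screened by ROC analysis against chance,
    dichotomized at Youden-optimal thresholds, summarised as positive and
    negative diagnostic likelihood ratios, and chained group by group into
    per-case post-test probabilities. Model evaluation includes ROC curves
    over posteriors, DeLong comparisons of correlated AUROCs, BCa bootstrap
    confidence intervals for sensitivity at fixed specificity, and predictive
    values at a given prevalence. A synthetic-cohort generator with known
    ground truth, emulating an ultra-high-risk psychosis cohort, supports
    testing and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, graphics, grDevices, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), pROC, boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
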