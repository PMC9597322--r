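Package: ssngrowth
Title: Longitudinal Growth Quantification and Prediction for Sub-Solid Pulmonary Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the growth of sub-solid pulmonary nodules (SSNs) on serial
    CT by mask-based diameter, volume and mass measurement, computes increase
    rates and doubling times, applies a mass-based growth criterion (at least a
    25 percent increase in mass per year), and predicts future growth from paired
    volumes of interest with a Siamese vision-transformer regressor trained with
    a class-weighted smooth-L1 loss, alongside a radiomics LASSO-logistic
    baseline. Includes a synthetic longitudinal nodule-phantom simulator with
    analytic ground truth, simplified rigid registration and nodule pairing,
    ROC/AUC evaluation with non-parametric bootstrap confidence intervals, and
    minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
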