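Package: genconn
Title: Generalized Functional Connectomes and Connectome-Based Predictive Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of generalized intrinsic functional connectomes from
    ROI time series (confound regression, spike and task regressors, zero-phase
    band-pass filtering, Pearson correlation, Fisher-z cross-run averaging),
    motion-based participant quality control, network-block connectivity
    summaries over a 17-network cortical parcellation with hippocampal ROIs,
    covariate-adjusted linear models of brain-behavior association, and
    connectome-based predictive modeling (CBPM) with nuisance-adjusted edge
    selection, leave-one-out cross-validation, permutation inference, selection
    threshold sweeps, and computational lesion analysis. Includes a synthetic
    cohort generator with planted edge-behavior effects so the full analysis
    chain can be exercised and validated without any scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
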