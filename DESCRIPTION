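Package: larfnet
Title: Gene Regulatory Network Inference by Lasso Random Featuring and
    Knockout Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from steady-state
    expression and single-gene knockout data.  Candidate regulations are
    scored by Gaussian mutual information, by z-scores of knockout-induced
    expression variation, and by LARF (lasso regression with random
    featuring, a selection-frequency score accumulated over a sweep of the
    L1 penalty with random candidate-regulator and sample subsets), and
    the criteria are combined by entry-wise matrix products (IMLARF,
    ISLARF).  Includes readers and writers for DREAM3-dialect expression,
    knockout and gold-standard files, ROC/AUROC evaluation of ranked edge
    lists, a parameter-grid protocol, a linear-Gaussian steady-state
    simulator of wild-type plus knockout benchmark data, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
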