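Package: wtpmxl
Title: WTP-Space Mixed Logit Analysis of Rewilding Choice Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stated-preference discrete choice experiments on
    landscape rewilding programs. Simulates choice data with
    political-affiliation covariates, estimates a willingness-to-pay (WTP)
    space mixed logit model by maximum simulated likelihood with scrambled
    Sobol draws, and produces the derived outputs used in applied work:
    per-party WTP tables with baseline shifts, status-quo choice shares,
    and a decomposition of preference heterogeneity into covariate-explained
    and residual parts with joint Wald tests per covariate group.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rlang,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
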