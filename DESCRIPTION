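Package: seldiff
Title: Diffusion Modeling of Selection-History Effects in Saccadic Pop-Out Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits the Ratcliff diffusion model to saccadic target-selection
    data from colour-oddball search with inter-trial priming (priming of
    pop-out and the distractor preview effect). Provides first-passage-time
    densities and distributions for the Wiener process between two absorbing
    boundaries, full-model predictions with trial-to-trial variability in
    drift, starting point and non-decision time, a condition-constraint
    scheme tying bias and drift changes to the preceding trial, a
    quantile-based chi-square fitting engine with nine-way sub-model
    comparison by AIC and BIC, a pseudorandom trial-sequence generator
    emulating the paired study design, a trial-level simulator for
    parameter-recovery experiments, and group-level statistics on fitted
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
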