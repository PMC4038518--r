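Package: rqcrm
Title: Robust Quasi-CRM Dose-Finding Designs for Toxicity Grades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phase I dose-finding with ordinal toxicity grades. Implements the
    quasi-Bernoulli continual reassessment method on equivalent-toxicity (ET)
    scores, with Bayesian model selection across multiple skeletons for
    robustness to skeleton misspecification. Includes posterior inference by
    deterministic Gaussian quadrature, safety stopping, a sequential trial
    simulator, and a Monte Carlo engine for operating characteristics
    (selection percentages, patient allocation, overdose exposure).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
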