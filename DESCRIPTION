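Package: twamatch
Title: Propensity-Matched Analysis of Intraoperative Hypotension Burden
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for retrospective, propensity-score-matched evaluation of
    intraoperative hypotension under advanced hemodynamic monitoring.
    Computes time-weighted-average (TWA) hypotension burden, episode counts
    and cumulative durations from fixed-interval mean-arterial-pressure
    series; fits logistic propensity models and performs greedy 1:1
    nearest-neighbor caliper matching with standardized-mean-difference
    balance diagnostics; builds group-comparison tables with
    normality-gated two-sample tests; classifies creatinine-based acute
    kidney injury; and ships a synthetic cohort generator that emulates the
    confounded treatment assignment and stochastic hypotensive-episode
    structure of perioperative registries, so the whole pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
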