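Package: rughc
Title: RUG-III/HC Case-Mix Classification and Resource Utilization
    Analysis for Home Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies home care episodes into the 23 Resource Utilization
    Groups version III for Home Care (RUG-III/HC) via the hierarchical
    classification algorithm with a configurable rule table, computes four
    case-mix indices (paid care time, paid care cost, combined paid and
    unpaid care time and cost, with unpaid caregiving valued at the
    replacement cost of a personal support worker) together with
    coefficients of variation, applies full-versus-operational sample
    trimming on episode length, and evaluates the variance in resource
    utilization explained by the case-mix system with linear models.
    Includes a synthetic cohort generator emulating transitional
    hospital-to-home care populations so every stage is testable without
    access to client-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
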