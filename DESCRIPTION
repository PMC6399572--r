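Package: teleCEA
Title: Trial-Based Cost-Effectiveness Analysis of Remote Video Consultations
Version: 0.1.0
Authors@R:
    person("teleCEA", "Maintainers", email = "maintainers@telecea.invalid",
           role = c("aut", "cre"))
Description: Economic evaluation toolkit for telemedicine outpatient services
    evaluated alongside a randomized trial. Implements equivalent-annual-cost
    annuitization of investments, component-based service costing with payer
    tags, travel-cost and production-loss valuation from consultation-level
    records, EQ-5D-3L utility scoring with a pluggable country tariff and
    QALY-gain outcomes, incremental cost-effectiveness synthesis with dominance
    classification and break-even consultation volumes, one-way sensitivity
    scenarios, cluster-aware between-arm comparisons (t test, chi-square,
    generalized estimating equations), and a seeded synthetic trial generator
    that reproduces the marginal structure of the motivating trial so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
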