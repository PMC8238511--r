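Package: oafiscal
Title: Fiscal Markov Cohort Modelling of Osteoarthritis Pain and
    Labour-Market Participation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A government-perspective (public-economic) Markov cohort model
    comparing labour-market participation, taxes, social-benefit transfers
    and health-care costs between cohorts with controlled and uncontrolled
    osteoarthritis pain. Provides validated age-banded participation inputs,
    odds-ratio to relative-risk conversion, tunnel-state transition matrices
    with state-pension-age rules, discounted net-present-value fiscal
    accounting and incremental net tax, one-way and probabilistic
    sensitivity analysis, declarative scenario analysis, and synthetic-data
    generators (Gompertz lifetables, participation tables, relative-effect
    sets) so the full pipeline runs without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
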