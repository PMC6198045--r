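Package: bphce
Title: Markov Cost-Effectiveness Model of Combination Therapy for Benign
    Prostatic Hyperplasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-arm Markov state-transition model comparing daily
    dutasteride/tamsulosin combination therapy against tamsulosin
    monotherapy for men with benign prostatic hyperplasia, from a
    healthcare-payer perspective.  Provides a deterministic cohort engine
    and a seeded individual-level microsimulation over seven health
    states, discounted cost and QALY accounting with per-category cost
    decomposition, incremental cost-effectiveness ratios and net monetary
    benefit, one-way deterministic sensitivity analysis (tornado), and
    probabilistic sensitivity analysis with cost-effectiveness plane and
    acceptability-curve output.  A synthetic-fixture module supplies toy
    chains with closed-form solutions and a calibrated Gompertz life-table
    stand-in for background mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
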