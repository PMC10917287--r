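Package: ckdcea
Title: Markov Cohort Cost-Effectiveness Modelling of SGLT2 Inhibition in
    Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A lifetime Markov cohort state-transition model for the
    cost-effectiveness of dapagliflozin added to standard of care versus
    standard of care alone in chronic kidney disease, from a health-system
    perspective.  Health states follow eGFR-defined CKD stages through
    dialysis and kidney transplantation to death, with monthly cycles,
    two-phase transition matrices, constant treatment discontinuation, and
    transient adverse events.  Provides discounted cost, QALY and life-year
    accounting, ICER and net monetary benefit comparison, one-way (tornado)
    deterministic sensitivity analysis, probabilistic sensitivity analysis
    with beta/gamma method-of-moments sampling, a per-individual
    microsimulation oracle for validation, and a synthetic parameter
    generator so the whole pipeline runs from packaged plain-text inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
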