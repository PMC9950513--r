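Package: btcea
Title: Markov Cohort Cost-Effectiveness Model for First-Line
    Immunochemotherapy in Advanced Biliary Tract Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-state (progression-free, progressed, dead) Markov cohort
    model comparing durvalumab plus gemcitabine/cisplatin against
    gemcitabine/cisplatin alone for advanced biliary tract cancer, from the
    US and Chinese payer perspectives. Provides closed-form parametric
    survival families with maximum-likelihood fitting and AIC/BIC selection,
    Kaplan-Meier curve digitization plumbing with Guyot-style individual
    patient data reconstruction, a trial-like synthetic data generator,
    time-dependent transition schedules with half-cycle corrected discounted
    life-year and QALY accumulation, a full cost and utility layer (drug,
    follow-up, adverse-event and subsequent-therapy costs), incremental
    cost-effectiveness statistics, one-way and probabilistic sensitivity
    analysis with tornado ranking, price-threshold search and
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
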