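Package: cadcea
Title: Markov Cohort Cost-Effectiveness Analysis of Starting Treatments for
    Stable Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for cohort Markov decision modelling of
    starting treatments for stable coronary artery disease (optimal medical
    therapy, stent percutaneous coronary intervention, coronary artery
    bypass grafting). Provides synthetic patient-record and billing
    generation under a known ground-truth chain, transition-probability
    estimation with Dirichlet count evidence, cumulative-incidence
    probability rescaling between cycle horizons, a discounted
    half-cycle-corrected cohort engine with a configurable background
    mortality increment, probabilistic sensitivity analysis over gamma and
    beta parameter distributions, and policy comparison via incremental
    costs, quality-adjusted life years, net monetary benefit,
    cost-effectiveness acceptability curves and population scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
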