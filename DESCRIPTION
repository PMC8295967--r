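Package: dceasmoke
Title: Distributional Cost-Effectiveness Analysis of Smoking-Cessation
    Interventions with Uncertainty Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An equity-stratified Markov cohort model of smoking-cessation
    interventions (varenicline, e-cigarette, no intervention) across English
    deprivation quintiles, with the uncertainty-analysis machinery of
    distributional cost-effectiveness analysis: incremental net health
    benefit with distributed health opportunity costs, Atkinson
    equally-distributed-equivalent health and the inequality impact
    (iEDE - iNHB), probabilistic sensitivity analysis, expected value of
    (partial) perfect information, and ANCOVA variance decomposition of
    PSA outputs.  Printed national and local-authority parameter tables are
    shipped as fixtures; externally sourced inputs the model needs but the
    literature does not print are emulated by a documented synthetic-data
    module so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    kernlab,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
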