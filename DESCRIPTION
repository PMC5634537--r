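Package: crvital
Title: Capture-Recapture Estimation of Underreported Law-Enforcement-Related Deaths
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying underreporting of law-enforcement-related
    deaths by linking a news-media-derived incident registry to vital
    statistics mortality records. Provides an auditable exclusion-rule engine,
    deterministic record linkage with stratified match-rate tables, two-list
    capture-recapture estimation via stratified Poisson log-linear models with
    a list-dependence offset and sensitivity analysis, analysis of ICD-10
    cause-of-death misclassification (cause grouping, stratified rate tables,
    nested random-intercept logistic regression, average marginal predicted
    probabilities), and a synthetic two-list death-registry generator so the
    full pipeline can be exercised and validated without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
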