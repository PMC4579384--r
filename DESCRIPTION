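Package: threshtrait
Title: Prevalence, Familial Association and Liability-Threshold
    Heritability for Binary Traits in Examination Registries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for retrospective cohort analysis of a binary inherited
    trait recorded in an eye-examination registry, motivated by canine
    distichiasis in the English Cocker spaniel.  Reads flat registry files,
    resolves per-dog affection status from repeated examinations, builds
    parent-offspring trio cohorts classified by parental mating type, and
    computes the standard familial-association statistics: prevalence, sex
    association, omnibus and pairwise continuity-corrected chi-square tests,
    relative risks, and continuity-corrected risk-difference confidence
    intervals.  Estimates heritability on the liability scale from group
    incidences with both the classical threshold-character regression and
    the variance-corrected estimator, with bootstrap intervals.  Includes a
    two-generation additive liability-threshold registry simulator with a
    closed-form incidence oracle so every pipeline stage is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
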