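Package: vitdmr
Title: Triangulated Observational and Mendelian Randomization Analysis of
    Vitamin D and Blood Pressure
Version: 0.1.0
Authors@R:
    person("HUNT", "Methods", email = "methods@example.org", role = c("aut", "cre"))
Description: A tested pipeline for triangulating the relationship between a
    serum biomarker (25-hydroxyvitamin D) and blood pressure outcomes using
    cross-sectional and prospective regression, split-sample one-sample
    Mendelian randomization with an externally weighted genetic risk score,
    summary-statistics two-sample Mendelian randomization (inverse-variance
    weighted, MR-Egger, weighted median, MR-PRESSO, Cochran's Q), and
    non-linear Mendelian randomization by residual and doubly-ranked
    stratification. Includes a synthetic-cohort generator emulating the
    statistical structure of a restricted population study so every stage is
    testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
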