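Package: lapref
Title: Hospital Profiling of Laparoscopic Surgery Preference and
    Risk-Adjusted Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling hospitals by their preference for
    laparoscopic over open surgery and relating that preference to
    risk-adjusted operative mortality in multi-hospital surgical
    registries. Provides reference logistic-regression machinery
    (iteratively reweighted least squares, likelihood-ratio tests,
    c-statistics), forward stepwise propensity modelling for the
    laparoscopic-versus-open choice, indirectly standardized
    observed/expected ratios for outcomes and for laparoscopy use with
    threshold-based preference categories, random-intercept hierarchical
    logistic regression fitted by adaptive Gauss-Hermite quadrature for
    volume-outcome and preference-outcome analyses, a translation of
    adjusted odds ratios into procedures per one excess operative death,
    and a synthetic multi-hospital registry generator for validating the
    whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
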