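Package: mvgtheory
Title: Multivariate Generalizability Analysis of Paired Operative Ratings
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for multivariate generalizability (G) theory analysis of
    workplace-based operative assessments in which a faculty surgeon and a
    trainee each rate autonomy and performance after a procedure. Implements
    a trainees-by-procedures random-effects design with four fixed-facet
    score variables: variance/covariance component estimation (closed-form
    expected mean squares on balanced data, REML on unbalanced data),
    composite decision (D) studies (generalizability coefficient, index of
    dependability, error variances, standard error of measurement, minimum
    number of procedures for a reliability threshold), dis-attenuated
    faculty-trainee correlations, dataset-construction rules (stratification,
    per-procedure sample-size threshold, balanced thinning), and a synthetic
    rating-data generator with known ground-truth components for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
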