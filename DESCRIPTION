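Package: cgmgrowth
Title: Growth-Curve Modeling from Cortical Growth Mark Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint estimation of population sigmoid growth curves and
    per-specimen relative start ages from cortical growth mark (CGM)
    series, as used in skeletochronology. Provides a registry of candidate
    sigmoid growth functions, least-squares clustering of overlapping
    series for objective start-age initialization, joint nonlinear least
    squares with AICc model selection, fractional-random-weight bootstrap
    simultaneous confidence bands with area-per-length metrics,
    leave-one-out compatibility screening, synthetic linear-series probes,
    nested dataset-variant comparison by same-points AICc with a Monte
    Carlo null test, circumference-to-body-mass conversion with growth
    rate metrics, and a synthetic CGM generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
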