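Package: hubpool
Title: Multi-Model Ensembles and Evaluation for Probabilistic Forecast Hubs
Version: 0.1.0
Authors@R:
    person("hubpool", "developers", email = "hubpool@example.org",
           role = c("aut", "cre"))
Description: Tools for combining probabilistic predictions from multiple
    models submitted to a collaborative forecast hub in a standardized
    tabular model-output format. Implements quantile (Vincent) averaging
    and the linear opinion pool for mean, median, quantile, CDF, PMF and
    sample output types, including reconstruction of full predictive
    distributions from a finite set of quantiles (monotone cubic spline
    interior, parametric normal/lognormal/Cauchy tails) and stratified
    pooling of joint samples. Also provides forecast evaluation (weighted
    interval score with its penalty decomposition, absolute error,
    prediction-interval coverage, relative skill versus a baseline) and a
    synthetic forecast-hub generator with closed-form ground truth for
    testing every ensembling and scoring path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
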