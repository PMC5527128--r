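Package: tcgam
Title: Trend-Level Analysis of Time-Course Metabolomics with Generalized
    Additive Models
Version: 0.1.0
Authors@R:
    person("tcgam", "maintainers", email = "tcgam@example.org",
           role = c("aut", "cre"))
Description: Fits generalized additive models to time-course metabolite
    concentration data using a shared "common" smoother plus a
    treatment-specific "differential" smoother (Gamma family with log link,
    REML smoothing selection), as used to analyse anthocyanin accumulation
    in elicited plant cell suspension cultures.  Includes cubic regression
    spline bases with exact second-derivative penalties, penalized IRLS
    fitting, Laplace-approximate REML smoothing-parameter selection,
    per-term effective degrees of freedom, approximate Wald-type tests and
    Bayesian credible bands, ratio-trend models, screening statistics
    (autoscaled PCA, Pearson correlation, per-timepoint Welch tests with
    Benjamini-Hochberg correction), a synthetic-data generator emulating
    the daily-sampled two-group elicitation design, and a command-line
    interface.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
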