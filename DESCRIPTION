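Package: invarimod
Title: Partial Metric Invariance and Tests of Latent Moderation in Single- and Two-Level SEM
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Monte Carlo machinery for studying how partial metric
    (factor-loading) non-invariance across two groups affects the estimation
    and Wald testing of latent moderation effects, for single-level
    two-factor structural equation models and for two-level models with a
    cross-level moderator. Provides population parameterizations with known
    (non)invariance structure, model-implied covariance algebra, seeded
    multivariate-normal data generators, constrained maximum-likelihood
    fitting of full- and partial-metric-invariance models with analytic
    gradients, expected-information and cluster-robust (sandwich) standard
    errors, Wald and likelihood-ratio contrasts on the group difference of
    the structural slope, and a replication harness that assembles empirical
    Type I error, power, and standardized-bias tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
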