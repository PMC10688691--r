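Package: ssripd
Title: Stress-Strength Reliability for the Inverse Pareto Distribution
    under Progressive First-Failure Censoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of the stress-strength reliability P(Y < X) when
    stress and strength are inverse Pareto lifetimes observed under
    progressive first-failure censoring. Provides the inverse Pareto
    distribution functions, censoring-scheme representation and sample
    generation, maximum product spacing and maximum likelihood point
    estimation, delta-method asymptotic confidence intervals, gamma-prior
    Bayesian estimation via component-wise Metropolis-Hastings with
    highest-posterior-density credible intervals, Kolmogorov-Smirnov
    goodness of fit, and a Monte Carlo study harness, together with two
    embedded reliability data sets (jute-fibre breaking strengths and
    electrical-insulation failure times) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
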