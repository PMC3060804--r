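Package: sppgof
Title: Sampled Posterior p-Values for Calibrated Bayesian Goodness-of-Fit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Internal goodness-of-fit checking for Bayesian models via the
    sampled posterior p-value (SPP) and its normalized variant (NSPP), in
    which all reference replicates are simulated from the likelihood at a
    single parameter value drawn from the posterior.  Also provides the
    classical comparator p-value engines (posterior predictive, prior
    predictive, plug-in maximum likelihood, half-sample maximum likelihood,
    and a frequentist SPP), a registry of discrepancy functions including
    test statistics on randomized-PIT normalized data, conjugate Poisson,
    Bernoulli and Normal model families, a simulation harness reproducing
    matched- and mismatched-prior calibration scenarios and a beta-binomial
    (Polya) power alternative, and uniformity diagnostics (Kolmogorov-
    Smirnov tests, randomized binomial tail tests, beta-posterior band
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
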