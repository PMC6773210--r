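Package: ltcens
Title: Censoring-Aware Analysis of Infant Looking-Time Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-level looking-time data from bimodal
    familiarization/test experiments with newborns, where looking times are
    right-skewed and ceiling-censored at the maximum trial length. Provides a
    synthetic-data generator reproducing the design, censoring and two-coder
    measurement structure of such studies; the classical inference stack
    (one-way and mixed-design repeated-measures ANOVA with partial eta squared,
    Tukey-adjusted marginal-mean comparisons, maximum-likelihood multilevel
    regression on raw and log-transformed responses); a four-variant Bayesian
    hierarchical model family (normal or log-normal likelihood, with censoring
    handled by latent-value augmentation or by integrating the likelihood
    beyond the ceiling) with credible intervals, Bayesian R-squared, posterior
    predictive cell intervals and within-subject difference posteriors; a
    cross-experiment aggregate censored log-normal model with nested contrasts;
    and simulation-based power analysis for design effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
Config/testthat/edition: 3
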