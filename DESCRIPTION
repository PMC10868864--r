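Package: twinace
Title: Classical Twin-Design Variance Decomposition for Early Alcohol-Use Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the classical same-sex twin design applied to binary and
    continuous behavioural phenotypes: cohort validation and zygosity-based
    exclusions, derivation of alcohol-sipping and alcohol-intent phenotypes
    from gated questionnaire items, cluster-adjusted descriptive statistics
    (Taylor-linearized proportions, first-order Rao-Scott chi-square,
    Cronbach's alpha), zygosity-specific pair correlations (Pearson/phi,
    intraclass, tetrachoric), moment (Falconer) and maximum-likelihood
    ACE/AE/CE/E variance-component models on pair-level likelihoods with a
    liability-threshold formulation for binary traits, BIC model comparison
    with boundary-driven reduction, a synthetic twin-cohort generator, and
    simulation-based power analysis for detecting additive genetic effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
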