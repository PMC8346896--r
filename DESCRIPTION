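Package: trajmix
Title: Group-Based Trajectory Models for Multicohort Arrest Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Group-based trajectory modeling (latent-class growth analysis)
    of longitudinal arrest counts: finite mixtures of Poisson age-trajectories
    with polynomial or spline rate curves and multinomial-logit group
    membership, optionally conditioned on baseline covariates.  Includes BIC
    model selection over the number of groups and functional forms,
    classification-adequacy diagnostics (average posterior probability, odds
    of correct classification), covariate odds ratios and profile membership
    probabilities with Rubin pooling across multiply imputed datasets,
    within-group arrest-rate tables by cohort and offense type with
    permutation tests, and a counterfactual decomposition of cohort
    differences in arrest rates into group-composition and within-group-rate
    components.  A fully specified synthetic multicohort generator emulates
    an unbalanced accelerated longitudinal design so every stage is testable
    without restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
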