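Package: gngtos
Title: Orthogonalized Go/No-Go Learning Under Threat of Shock
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for an approach-withdrawal
    Go/No-Go task performed under alternating safe and threat-of-shock
    blocks. Provides a generative task simulator (balanced schedules,
    probabilistic outcome delivery, fixed-position shock events), the
    nested Rescorla-Wagner model family with Pavlovian bias (m1-m4),
    hierarchical Bayesian MCMC fitting per task condition with PSIS-LOO
    model comparison and highest-density-interval inference on
    hyperparameter differences, and the behavioral statistics layer
    (repeated-measures factorial ANOVA with Greenhouse-Geisser
    correction, FDR-corrected paired contrasts, manipulation checks,
    and paired t-test power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
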