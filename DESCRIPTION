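Package: igtbayes
Title: Bayesian Analysis of Group Differences in the Iowa Gambling Task
Version: 0.1.0
Authors@R:
    person("IGT", "Modelers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A toolkit for comparing two groups of Iowa Gambling Task (IGT)
    decision-makers with the PVL-Delta reinforcement-learning model.
    Provides the traditional IGT payoff environment, the PVL-Delta
    likelihood and simulator, Bayesian hierarchical parameter estimation
    on the probit scale, product-space (Carlin-Chib) Bayes factor
    comparison across the sixteen group-difference model specifications,
    informed-prior latent-mixture inference of group membership, post hoc
    absolute-fit (one-step-ahead) adequacy checks, and a synthetic-data
    generator with known ground truth for end-to-end validation. All
    samplers are custom Metropolis-within-Gibbs implementations with
    compiled likelihoods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
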