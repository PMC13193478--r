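Package: leafhabit
Title: Eco-Evolutionary Analysis of Dry-Season Deciduousness on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether a binary leaf-habit trait (deciduous versus
    evergreen) shaped lineage diversification and environmental-niche evolution,
    and to identify its environmental predictors. Implements time-stratified
    state-dependent speciation-extinction (SSE) likelihoods with hidden states
    and epoch-varying transition rates, multi-regime Brownian-motion and
    Ornstein-Uhlenbeck niche-evolution model selection over stochastic character
    maps (AICc and Akaike weights), and a Bayesian phylogenetic multilevel
    Bernoulli regression fitted by an exact Polya-Gamma Gibbs sampler, with
    Bayesian R-squared, posterior predictive checks and prior power-scaling
    sensitivity. Includes occurrence cleaning, convex-hull ranges, random point
    generation, spatial thinning, environmental extraction, collinearity
    screening, seeded synthetic-data generators for every stage, and a pipeline
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    geosphere,
    grDevices,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    phytools,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
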