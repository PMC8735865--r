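Package: seqvol
Title: Sequence Prediction Agents for Stochastic, Changing, and Structured
    Binary Environments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulators and agents for binary sequence prediction in volatile
    environments whose latent Bernoulli (unigram) or transition (bigram)
    probabilities are resampled at hidden change points. Provides the exact
    Bayesian observer via hidden-Markov forward filtering on a discretised
    probability grid, delta-rule and leaky-integration heuristics with
    gradient-fitted learning rates, and four small recurrent network
    architectures (gated recurrent and three ablations) trained by
    backpropagation through time with Adam. Includes the accompanying
    analysis suite: percent-of-optimal performance, moment-by-moment
    effective learning rate, linear readouts of latent-variable estimates
    and their precision, mutual information, constrained activity
    perturbations, higher-level change-point inference probes, and
    complexity scaling with power-law fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
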