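Package: lifemix
Title: Demographic Outcomes and Variance Decomposition for Finite-Mixture
    Life Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stage-classified absorbing Markov chain analysis of life
    histories with fixed unobserved heterogeneity modelled as a finite
    mixture of discrete groups. Builds column-stochastic transition
    matrices from stage-specific survival, breeding and success
    probabilities; computes Markov chain demographic outcomes per group
    (fundamental matrix, stage occupancy and its variance, longevity,
    lifetime reproductive output, conditional first-passage times such as
    age at recruitment and inter-breeding intervals); projects
    heterogeneous cohorts with the vec-permutation block formulation;
    decomposes inter-individual variance in any outcome into individual
    stochasticity (within-group) and heterogeneity (between-group)
    components; and provides an individual-based Monte Carlo simulator of
    the same mixture model for validation and for generating synthetic
    capture histories. Ships the published model-averaged vital rates for
    the southern fulmar (Fulmarus glacialoides) at Ile des Petrels as a
    worked fixture.
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
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
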