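Package: serialrep
Title: Serial Reproduction Chains and Bayesian Observer Models of Visuospatial Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analyzing serial-reproduction
    (transmission-chain) experiments on remembered point locations.
    Implements three Bayesian observer models on discrete spatial grids
    (fixed precision, symmetric variable precision, and efficient encoding
    via a prior-uniformizing coordinate warp), the induced Markov chain over
    reproductions and its stationary-distribution diagnostics, predicted and
    empirical discrimination (d') maps from two-alternative forced-choice
    data, nonparametric and parametric kernel density estimation of spatial
    priors from chain data, the category adjustment model baseline, bias
    vector-field statistics with bootstrap inference, and a synthetic
    experiment generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), png, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'grid.R'
    'observers.R'
    'chain.R'
    'bias_stats.R'
    'discrimination.R'
    'estimators.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
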