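Package: wmattractor
Title: Attractor-Network Model of Working-Memory Match Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spiking and mean-field implementations of an attractor network
    model of working memory in which match enhancement and match suppression
    both arise from the modulation of network excitability by persistent
    activity. Provides a leaky integrate-and-fire network with NMDA/AMPA/GABA
    current kinetics and structured excitatory connectivity, mean-field
    self-consistency equations with Newton-Raphson fixed points (spontaneous
    and delay states, bifurcation scans in the potentiated efficacy), a
    simplified four-population rate dynamics, delayed match-to-sample
    protocols with and without intervening distractors, and the analysis
    statistics used to characterise match effects: 200 ms response counts,
    sparseness indices, enhancement/suppression/match-non-match indices,
    suppressed fractions, tuning curves and sample-delay correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
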