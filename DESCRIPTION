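Package: lzphi
Title: Signal Diversity, Integrated Information, and Directed Network
    Topology for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures of spontaneous-EEG complexity and integration for
    anesthesia research: Lempel-Ziv signal diversity (LZs), amplitude and
    synchrony coalition entropy (ACE, SCE), Welch spectra and the 20-40 Hz
    spectral exponent; Gaussian-approximation integrated-information
    measures (multi-information, mutual integrated information, stochastic
    interaction, decoder-based phi-star, geometric phi-G) with Queyranne
    minimum-information-partition search and hierarchical complex search;
    directed functional connectivity via order-4 multivariate
    autoregressive models and the directed transfer function, with global
    efficiency and directed-weighted Louvain modularity; condition
    contrasts (Wilcoxon signed-rank, Spearman) and a seeded autoregressive
    network simulation study relating the measures to ground-truth network
    topology. Includes a synthetic rat-like EEG generator so the whole
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
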