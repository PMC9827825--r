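Package: ersnet
Title: Graph-Based Elementary Reaction Step Enumeration and Reaction
    Network Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated exploration of chemical reaction networks
    built on graph-based elementary reaction steps (ERS). Molecules are
    represented as valence-valid molecular graphs over C, H, N, O, S and P;
    candidate products are enumerated by breaking and forming integer
    bond-order units (bNfM steps such as b2f2 and b3f3), pre-pruned by
    bond-increment heats of reaction, and characterized through a pluggable
    transition-state backend (a deterministic surrogate and a replay backend
    for archived characterization records). Converged transition states are
    classified as intended or unintended from their intrinsic reaction
    coordinate endpoints, unintended channels are mined back into the
    network, and recursive exploration assembles a reaction network
    supporting minimax (lowest-maximum-barrier) pathway analysis and
    standard performance statistics: success rate, intended rate, gradient
    calls, and gradient calls per intended product.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
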