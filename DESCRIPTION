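Package: reefbeta
Title: Abundance-Based Beta Diversity of Reef-Associated Soft-Bottom Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying compositional variation (beta diversity)
    among benthic community samples from specimen count tables. Implements
    pairwise proportional dissimilarity (relative Bray-Curtis) and the
    modified Gower measure, a gamma-pool multinomial resampling null model
    for community assembly, alpha-diversity indices (Berger-Parker dominance,
    Shannon, Pielou evenness), distance decay of similarity, one-factor
    PERMANOVA, principal-coordinates and non-metric multidimensional scaling
    embeddings, multivariate dispersion with the imaginary-axis correction,
    and a synthetic metacommunity generator with tunable depth niches and
    site idiosyncrasy for validation by parameter recovery. Ships the
    published specimen counts, sample metadata, and dissimilarity matrices
    of a Triassic (Cassian Formation) and a modern (Bay of Safaga, Red Sea)
    reef-basin dataset as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
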