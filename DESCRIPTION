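Package: grazenet
Title: Trophic and Non-Trophic Interaction Networks Between Mollusk
    Grazers and Biofilm Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies per-capita trophic and non-trophic effects of
    intertidal mollusk grazers on epilithic biofilm bacterial communities
    from 16S amplicon count tables. Implements centered log-ratio
    compositional transforms, Dynamic Index interaction-strength
    estimation with bootstrap confidence intervals, decomposition of
    total grazer effects into trophic (grazing) and non-trophic (pedal
    mucus) components, construction of signed weighted bipartite
    grazer-by-ASV networks, a suite of nestedness metrics (NODF, weighted
    NODF, WNODA, WINE, matrix temperature, discrepancy) and Bluethgen
    specialization indices (H2', d') implemented from their primary
    definitions, community-level statistics (rarefaction, richness,
    Shannon diversity, Bray-Curtis, PERMANOVA), and a Dirichlet-
    multinomial experiment simulator with known ground truth for
    estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
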