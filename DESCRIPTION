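Package: amfdiv
Title: OTU Clustering, Taxon Calling and Diversity Analysis for
    Arbuscular Mycorrhizal Fungus Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable, testable pipeline for molecular identification and
    biodiversity analysis of arbuscular mycorrhizal fungi (Glomeromycota)
    from ITS1/ITS2 amplicon reads: paired-read merging and expected-error
    filtering, two-step OTU construction (closed-reference mapping to
    database centroids at 97 percent identity followed by abundance-greedy
    de novo clustering with chimera removal and an asymmetric singleton
    policy), genus-binned neighbor-joining trees with explicit clade
    decision rules emitting species calls and species-level virtual taxa,
    Hill-number diversity with asymptotic (Chao-type) estimators and
    bootstrap confidence intervals, and the community-level statistics
    (total-sum scaling, correlation matrices, ANOSIM, ordination, Ward
    clustering) used to relate fungal diversity to site metadata. A
    synthetic-community generator with ribotype heterogeneity, chimeras,
    singletons and planted metadata correlations stands in for field
    samples and reference databases so that every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
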