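Package: tina
Title: Interaction-Adjusted Indices of Community Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies beta diversity of ecological communities in the
    context of taxa interaction networks. Implements the Taxa
    INteraction-Adjusted (TINA) and Phylogenetic INteraction-Adjusted
    (PINA) community similarity indices together with the classical
    count-based indices (Jaccard, Chao-Jaccard, Bray-Curtis,
    Morisita-Horn) and UniFrac they are benchmarked against. Provides
    taxa co-occurrence network inference (SparCC, Spearman, taxa-wise
    Bray-Curtis and weighted Jaccard), the canonical profile-correlation
    association transform, PERMANOVA and principal-coordinates analysis
    on distance matrices, and generalized Lotka-Volterra simulation
    engines for generating habitat-structured benchmark communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    phangorn,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
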