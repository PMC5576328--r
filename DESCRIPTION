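Package: mbpairs
Title: Concordance Analysis of Paired Microbiota Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether two sampling methods applied to the
    same subjects recover the same microbial community, built around paired
    16S rRNA amplicon surveys of induced versus spontaneous sputum in COPD.
    Implements Yue-Clayton dissimilarity and Bland-Altman limits of agreement
    on paired taxon profiles, per-taxon log-likelihood ratio (G) tests with
    Bonferroni correction, rarefaction, alpha diversity (observed OTUs,
    Chao1, Faith's phylogenetic diversity) with permutation group tests,
    unweighted and weighted UniFrac with Monte-Carlo pair significance,
    principal coordinates analysis with Procrustes superimposition and
    ANOSIM, per-pair concordance classification, and a seeded generator of
    synthetic paired community datasets for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    biomformat,
    stats,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    phangorn,
    phyloseq,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
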