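Package: assocnet
Title: Microbe-Metabolite Association Networks from Paired Microbiome
    Feature Tables
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds cooccurrence association networks that link microbial
    features (OTUs or biosynthetic gene cluster families) to LC-MS molecular
    features across many microbiome samples.  Provides presence/absence
    association by a vectorized two-sided Fisher's exact test (with Pearson,
    Spearman and mutual-information alternatives), false-discovery-rate
    control by a target-decoy approach and by Benjamini-Hochberg, m/z
    tolerance deduplication of redundant molecular features, bipartite
    association-network construction and export, and assignment of molecules
    to minimal phylogenetic clades.  A synthetic paired-data generator with
    planted associations and planted duplicate clusters supports calibration
    and benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
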