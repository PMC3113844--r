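Package: rhonet
Title: Median-Joining Haplotype Networks and Rho-Statistic Dating for
    mtDNA Control-Region Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of human mitochondrial control-region
    haplotypes encoded as rCRS-relative variants: parsing and trimming of
    variant tables, mutation-rate-based site weighting with hotspot
    exclusion sets, weighted median-joining network reconstruction with
    maximum-parsimony post-processing and back-mutation accounting,
    rho-statistic TMRCA estimation with the Saillard variance under
    genealogical and phylogenetic rate conventions, great-circle dispersion
    comparison of ancestral versus derived lineages via the Mann-Whitney U
    test, and a synthetic-data generator producing haplotype panels with
    heterogeneous per-site rates and geographically structured sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
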