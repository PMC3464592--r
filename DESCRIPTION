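Package: dupscan
Title: Gene Duplication Set Detection and Divergence Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects duplicated gene sets in an annotated genome by all-vs-all
    protein similarity and Markov clustering, classifies sets as tandem,
    intra-chromosomal or inter-chromosomal from gene coordinates, estimates
    pairwise synonymous (Ks) and nonsynonymous (Ka) divergence with the
    Nei-Gojobori counting method under a Jukes-Cantor correction, profiles
    duplication-set size and Ks age distributions, tests GO-term enrichment
    among recent duplicates with Fisher's exact test, and simulates
    shotgun-assembly collapse of near-identical paralogs. Ships a synthetic
    genome generator that plants duplication sets of known size, type and
    target Ks so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
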