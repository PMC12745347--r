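Package: charrcu
Title: Conservation Genomics of Highly Structured Lake Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end conservation-genomics toolkit for SNP datasets from
    strongly drifted lake metapopulations such as Arctic charr (Salvelinus
    alpinus). Provides a replicate-aware SNP quality-control cascade, diversity
    and differentiation statistics (Weir-Cockerham F_ST, Weir-Goudet
    population-specific F_ST, private alleles, nucleotide diversity),
    population structure analyses (PCA, neighbor-joining trees with locus
    bootstrap, hierarchical AMOVA, F_ST-threshold clustering), redundancy
    analysis based genotype-environment association screens with collinearity
    pruning and interval annotation of candidate loci, a gradient-forest-style
    turnover model yielding per-lake genetic offset under future climate
    scenarios, composite lake-sensitivity scoring, and rule-based delineation
    of management units and evolutionarily significant units. A hierarchical
    Balding-Nichols metapopulation simulator generates genotype, population-map
    and environment inputs with known truth so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    geosphere,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
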