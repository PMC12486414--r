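Package: GeneSurvey
Title: Environmental Survey Pipeline for Functional Gene Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for environmental surveys of a functional
    marker gene (built around the copper nitrite reductase gene nirK):
    deduplication and domain-specific length filtering of annotated gene
    sequences, greedy identity-threshold clustering (CD-HIT style, 87%
    default), per-cluster consensus building from center-star alignments,
    extraction of the maximal-overlap alignment window across clusters and
    individual sequences, archetype/OTU assignment on the window region,
    environmental-source niche statistics (single-source OTU fractions,
    per-source and per-taxon percentage tables, rank-abundance curves), and
    neighbor-joining phylogenies of OTU representatives. A synthetic survey
    generator with planted family structure, fragment models and
    source-specificity makes every stage testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    withr
biocViews: Sequencing, Alignment, Clustering, Phylogenetics, Metagenomics,
    Microbiome
Config/testthat/edition: 3
RoxygenNote: 7.3.3
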