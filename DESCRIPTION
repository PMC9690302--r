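Package: chloronet
Title: Comparative Chloroplast Genomics and Consensus Gene Regulatory
    Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing annotated chloroplast genomes across
    population samples and for linking sequence polymorphism to regulation.
    Parses GenBank flat files, locates the inverted repeats and derives the
    quadripartite LSC/SSC/IR partition, summarises genome features, builds
    cross-sample gene presence/absence matrices with Jaccard clustering,
    classifies polymorphic genes into location-specific groups from
    per-gene alignments, and concatenates supergenes for phylogenetic
    input. Infers a modular regulator-to-target network from expression
    data by greedy per-target regression with a module-consistency prior,
    stabilises it by subsample consensus with per-edge confidence, and
    tests target sets for term enrichment with two-tailed Fisher tests and
    Benjamini-Hochberg false discovery rate control. Seeded generators
    simulate every input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
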