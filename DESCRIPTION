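Package: PromoterForge
Title: Model-Guided Design of Yeast Promoters from Sort-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for building artificial Saccharomyces
    cerevisiae promoters from massively parallel reporter data. Promoter
    libraries are described as scaffolds of constant motifs and randomized
    spacers; per-variant activities (log10 GFP:mCherry) are inferred from
    binned FACS-seq cell counts by maximum likelihood under a normal-plus-
    uniform-contaminant mixture; error-bearing reads are reduced to consensus
    sequences by sort-based clustering with Needleman-Wunsch distances; an
    ensemble of convolutional sequence-to-activity models is trained on the
    resulting activity tables; new promoters are designed by screening,
    in silico evolution or gradient ascent under GC-content and restriction-
    site constraints; and designed sequences are characterized by in silico
    saturation mutagenesis. A synthetic-data module simulates the full sort-
    and-sequence experiment so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    tools,
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
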