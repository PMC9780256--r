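Package: mutpatterns
Title: Sequence-Context Mutation Rate Models via IUPAC Pattern Partitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds extended sequence-context models of germline point-mutation
    and indel rates by partitioning the space of k-mers with IUPAC ambiguity
    patterns, fitted by an exact dynamic program or a greedy heuristic under a
    penalized binomial deviance. Includes k-mer counting with strand collapsing
    and randomized indel breakpoint placement, hyperparameter selection by
    repeated two-fold cross-validation with hypergeometric table splits,
    Nagelkerke pseudo r-squared evaluation, and a gene-level engine that
    converts a fitted rate model into expected counts of functional mutation
    classes per transcript, Poisson-binomial burden p-values, and
    loss-of-function constraint scores. A seeded synthetic-data generator
    produces toy genomes, masks, annotations and mutation sets for testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR,
    withr
Config/testthat/edition: 3
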