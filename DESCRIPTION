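Package: tcis
Title: Isoform Switch Detection and Splicing-Aware Analysis for Time-Course Transcriptomics
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and scores isoform-switch events in time-course
    isoform expression data. Provides relative-abundance computation,
    switch-point detection across replicates, event metrics (switching
    probability, difference of relative abundance, event importance,
    dissimilarity coefficient, replicate support), rank-based and
    permutation significance testing with multiple-testing correction,
    protein-domain gain/loss annotation, clustering of genes by change of
    total isoform usage, splicing-factor co-expression and PSSM motif
    enrichment, a ground-truthed Dirichlet/Markov-chain count simulator,
    and a precision/recall benchmarking harness with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    matrixStats,
    cluster,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    yaml
Config/testthat/edition: 3
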