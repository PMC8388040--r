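Package: pangaln
Title: BLAST-Like Local Alignment Search in Colored de Bruijn Graph Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds statistically significant local alignments between DNA query
    sequences and a pangenome stored as a compacted colored de Bruijn graph.
    Provides graph construction from genome FASTA files, a cumulative-profile
    w-mer occurrence index, quorum and search-color-set constrained seed-and-extend
    alignment with X-drop ungapped extension over truncated graph paths, banded
    gapped recomputation with color-set checkpoints, and exponential-tail score
    statistics (E-values and p-values) calibrated by naive sampling and
    Metropolis-Hastings importance sampling. A synthetic pangenome and query
    simulator supports fully self-contained analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    tibble,
    dplyr,
    jsonlite,
    stats,
    utils,
    Biostrings,
    ggplot2,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
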