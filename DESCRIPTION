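Package: ssmotif
Title: Simple Shared Motifs in Conserved Promoter Regions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects putative co-regulation between genes by counting Simple
    Shared Motifs (SSMs): maximal sets of short, strand- and
    orientation-degenerate subsequences shared between the evolutionarily
    conserved promoter motifs ("atomic motifs") of a gene pair. Each DNA word
    is treated as an equivalence class closed under complementation, reversal
    and reverse-complementation, with a min-over-members Hamming metric;
    SSMs are the maximal cliques of the resulting similarity graph that span
    both genes. SSM counts are normalised by the number of potential
    length-l windows (SSMC), scored against empirical null distributions
    built from random gene pairs, and combined across (length, distance)
    motif types into cp-values and CEXlists of candidate co-regulated genes.
    Includes downstream gene-set over-representation statistics
    (hypergeometric tests, c-scores and z-scores against random-list nulls,
    co-expression density and Fisher in/out enrichment), a synthetic motif
    database generator with planted co-regulated modules for benchmarking,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stringi,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
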