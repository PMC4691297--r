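Package: genicssr
Title: Mining and Comparative Analysis of Microsatellites in Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects perfect simple sequence repeats (SSRs, microsatellites)
    with motif lengths 1-10 bp in coding sequences, classifies them into the
    long (class I) and short (class II) marker classes via per-motif-length
    minimum repeat-count thresholds, collapses motifs into canonical classes
    under circular permutation and reverse complement, and aggregates loci
    into per-megabase density, nucleotide-composition and encoded amino-acid
    tables. Includes the equal-expectation chi-square heterogeneity test used
    to compare SSR densities within and between gene catalogs, a Welch t-test
    on tract lengths, and a synthetic CDS generator that plants ground-truthed
    repeat tracts in repeat-free background for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
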