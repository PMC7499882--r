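Package: ccdbg
Title: Colored and Compacted de Bruijn Graphs from Reads and Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds the compacted de Bruijn graph (cdBG) of a set of
    sequencing reads or assembled genomes directly, without materialising the
    uncompacted graph. K-mers are filtered through two blocked Bloom filters
    (k-mers seen at least twice survive in reads mode), unitigs are extracted
    from the filter with ghost k-mer protection against false-positive
    fragmentation, and residual false-positive k-mers are removed by
    counter-based elimination so the final graph is exact. The graph is
    indexed by a minimizer hash table supporting exact k-mer lookup, dynamic
    insertion and removal of unitigs, and updates with new samples. An
    optional color layer records, for every k-mer, the subset of input
    datasets it occurs in, using tiered per-unitig containers. Sequence
    queries report per-query k-mer inclusion ratios with a presence
    threshold, exactly or allowing one substitution or indel per k-mer, and
    graphs are serialised as GFA 1.0. A seeded synthetic-dataset generator
    (genomes, mutated variants, error-bearing reads) supports testing and
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
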