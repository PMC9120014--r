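Package: crcscape
Title: Super-Enhancer Landscapes and Core Regulatory Circuitry Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subtyping cell populations from enhancer-mark ChIP-seq
    data. Calls super-enhancers from H3K27ac peaks and signal tracks by rank
    ordering with a tangent cutoff, assigns them to genes, scans transcription
    factor binding motifs in extended super-enhancer windows with exact
    p-value thresholds, builds per-sample core regulatory circuitry (CRC) as
    fully interconnected auto-regulatory transcription factor cliques, and
    compares CRC networks across samples with a three-term structural
    dissimilarity measure (distance-distribution divergence, node dispersion,
    and alpha-centrality divergence on the graph and its complement) followed
    by hierarchical clustering into subgroups. Includes a deterministic
    synthetic-cohort generator with planted super-enhancers and planted
    cliques for end-to-end validation, plus broad-domain ranking and
    super-enhancer versus typical-enhancer binding statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
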