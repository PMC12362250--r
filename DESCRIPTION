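Package: trnamod
Title: Detection of tRNA Modifications from Nanopore Modification-Caller Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting RNA modifications on tRNAs from nanopore
    direct-RNA sequencing. Decodes per-read modification prediction scores
    from SAM base-modification (MM/ML) tags, aligns reads to adapter-flanked
    mature tRNA references with an affine-gap local aligner and a three-rule
    alignment filter (best score per read, minimum alignment score,
    full-length body coverage), calls pseudouridine de novo via a per-site
    high-score fraction statistic, detects arbitrary ("off-label")
    modifications by comparing smoothed per-site score histograms between
    samples with a symmetric Kullback-Leibler divergence, applies
    Tukey's-fences outlier calling to per-position basecalling-error scores,
    and extracts per-base raw-signal segments from basecaller move tables
    for comparative visualization. A seeded simulator emulates every input
    so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
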