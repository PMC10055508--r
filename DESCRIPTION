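Package: spcenrich
Title: Tissue-Enriched Protein Discovery from Spectral Counts by In
    Silico Reference Subtraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A label-free proteomics pipeline for prioritizing
    tissue-enriched proteins by comparing spectral counts against a
    whole-body reference proteome ("in silico subtraction").  Covers
    target/decoy PSM filtering to an experiment-wide FDR with
    conditional score histograms, parsimony-based protein inference
    with extended grouping of homologous families, spectral-count
    tallying and scaling, TMM normalization, a conditional
    negative-binomial exact test with qCML common dispersion,
    Benjamini-Hochberg correction, MA-band enrichment calls, QC
    summaries, and UCSC custom-track export.  Includes a seeded
    synthetic-data generator (decoy databases, PSM tables, count
    matrices with planted enrichment) so every stage is testable
    without raw mass-spectrometry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    grDevices,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
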