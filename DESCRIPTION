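Package: lncloc
Title: Determinants of lncRNA-Chromatin Interaction Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis pipeline for long non-coding RNA (lncRNA)
    chromatin interaction maps of the GRID-seq/RADICL-seq kind. The genome is
    segmented into fixed-width tiles and, for every sufficiently covered
    lncRNA, bound tiles are discriminated from distance-matched unbound tiles
    with random-forest classifiers built on sequence and cell-context feature
    families (k-mer counts, motif scans, repeat overlaps, triplex formation
    potential, shared motifs, accessibility, methylation, chromatin marks,
    TF ChIP and transcription). Genomic block cross-validation controls
    spatial leakage; feature-family importance is quantified by Marginal and
    Maximal Predictive Value over power sets of family combinations, with
    pairwise complementarity scores, fine-grained Gini-rank aggregation,
    signed Kolmogorov-Smirnov enrichment statistics and k-mer density
    correlation analyses. A synthetic-data generator with planted
    transcription-, triplex- and XOR-type signals makes the whole pipeline
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
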