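Package: apakit
Title: Alternative Polyadenylation Analysis from RNA-seq, Microarray and
    CLIP Coverage Data
Version: 0.1.0
Authors@R: person("APA", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies alternative polyadenylation (APA) from short-read
    data. Builds split 3'UTR annotations at proximal polyA sites from a
    polyA-site database, counts strictly contained reads, computes RPKM
    and distal-3'UTR (d3'UTR) usage ratios, classifies condition-sensitive
    genes by a binned Z-score fold-change criterion, scores tissue
    restriction with cosine SPM/CTM statistics, performs probe-level
    microarray d3'UTR screens with a chi-squared imbalance test, runs
    classic-scheme gene set enrichment analysis with leading-edge
    summaries, profiles coverage around polyA sites, analyses
    transcription-shutoff decay time courses, and ships a synthetic-data
    generator with planted ground truth plus an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
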