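Package: peakdedup
Title: Signal-Aware Duplicate Handling for ChIP-seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies read duplication in ChIP-seq libraries separately for
    peaks, peak flanks and the non-peak genome, and partitions in-peak
    duplicates into natural (signal) duplicates and PCR (noise) duplicates.
    Natural duplicates arise when independent DNA fragments share a mapping
    position and strand, which is frequent inside narrow peaks; PCR duplicates
    are amplification artifacts. The partition caps the duplicate count per
    position, predicts the natural duplicate level of each peak from its
    target enrichment level (nonredundant reads per kb) with robust local
    regression, and keeps the smaller of the observed and predicted levels.
    A properly deduplicated alignment file retains the predicted signal
    duplicates inside peaks while removing all other duplicates. Includes the
    full duplicate-accounting QC suite (duplicate rate, NRF, FRiP, RPK10M,
    confidence-group profiles, top duplicated positions, replicate and
    feature correlations) and a synthetic ChIP-seq library simulator with
    per-read duplicate ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
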