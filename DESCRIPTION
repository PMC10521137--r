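Package: traelkit
Title: Replication-Fork Progression, Proximity-Labelling Enrichment and
    Nuclear-Fluorescence Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of DNA replication-fork progression from
    TrAEL-seq (Transferase-Activated End Ligation sequencing) read ends:
    single-nucleotide break-end extraction, exclusion-mask filtering, running-
    window reads-per-million signal, active-origin calling, origin-centred
    oriented probes with local-polynomial (Loess) smoothing, prominence-based
    peak detection, fork-distance and origin-firing statistics with one-way
    ANOVA and multiple-comparison corrections. Also implements control-protein
    normalised label-free-quantification (LFQ) enrichment scoring for
    TurboID/BioID proximity-labelling experiments, and corrected total nuclear
    fluorescence with nuclear/cytoplasmic ratio comparisons. Ships seeded
    synthetic-data generators with ground truth for every stage, and pipeline
    drivers with provenance tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
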