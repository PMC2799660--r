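Package: nuctf
Title: Nucleosome Occupancy Maps and Transcription Factor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating nucleosome occupancy to transcription
    factor (TF) binding in compact genomes such as yeast. Builds
    per-basepair occupancy tracks from nuclease-protection tag starts or
    bedGraph coverage, normalizes, window-averages ("blurs") and
    symmetrizes them, and forms crosslinked-minus-uncrosslinked
    nucleosome difference maps. Associates occupancy with ChIP-defined
    binding via Mann-Whitney ROC AUC with bootstrap confidence
    intervals, quantifies the effect of resolution via window-size
    deltas, computes qPCR fold enrichments from delta-delta-Ct tables,
    clusters per-TF occupancy profiles by k-means on Pearson
    similarity, and scores promoters with a thermodynamic position
    weight matrix model optionally weighted by local or regional
    nucleosome occupancy. A synthetic-data module generates genomes,
    planted motif sites, tag maps and qPCR tables with known ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
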