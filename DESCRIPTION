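Package: chromredist
Title: Differential Chromatin-Mark Redistribution Analysis on Tiling Signal Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects redistribution of repressive chromatin marks (H3K9me2,
    H3K27me3) between genotypes from normalized tiling-array signal tracks.
    Provides log2-ratio normalization, sliding-bin z-score region calling with
    merge and length rules, a probe-level block caller for broad domains,
    circular-permutation false discovery rate estimation, gene assignment by
    minimum overlap, Class I/II gene classification, scaled metagene
    (TSS-TTS) profiling of ChIP signal, cytosine methylation and read
    density, RPKM-based expression summaries, sequence-composition metrics,
    and a seeded synthetic-epigenome generator with planted mark
    redistribution used to validate every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
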