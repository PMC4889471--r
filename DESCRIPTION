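Package: chromsig
Title: Co-Occupancy and Chromatin-Signature Analysis for ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide co-occupancy analysis of transcription-factor and
    histone-mark ChIP-Seq peak sets: at-least-1-bp overlap classification
    between two factors, peak-to-gene target assignment, TSS-relative and
    peak-centered meta-profiles with max-100 and per-100-anchor
    normalizations, promoter occupancy classification for repressive
    chromatin marks, and a rule-based caller that labels serial qChIP
    series with one of two epigenetic repression signatures. A
    scenario-driven synthetic-data generator plants exact overlap,
    target-gene and promoter-class structure so the whole pipeline can be
    verified end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    methods,
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
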