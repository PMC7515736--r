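Package: dapcompare
Title: Comparative Analysis of seq-DAP-seq Transcription Factor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream comparative analysis of sequential DNA-affinity
    purification sequencing (seq-DAP-seq) experiments for transcription
    factor complexes. Pools replicate peak calls into width-normalized
    consensus peaks, compares dimeric and tetrameric complexes through a
    union peak catalogue and the coverage fold reduction (CFR), trains
    0-order position weight matrices and first-order transcription factor
    flexible models (TFFM) on top-ranked bound regions, evaluates them by
    AUROC against GC- and origin-matched unbound regions, quantifies
    CArG-box intersite-spacing enrichment indicative of cooperative
    tetramer binding, and determines bound-and-regulated target genes by
    intersecting binding with differential-expression data. Ships a
    synthetic-data generator with recorded ground truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
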