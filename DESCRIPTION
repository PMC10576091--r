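Package: loopregnet
Title: Differential Chromatin Regions, Promoter Loops and Regulatory Networks by Presence/Absence Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-omics integration toolkit for case/control epigenome panels
    (one control line versus many tumour-derived lines). Implements
    multi-sample consensus segmentation of peak calls with lost/gained
    presence-absence rules, HiChIP loop post-processing (filtering, anchor
    unification, differential calling, promoter/enhancer classification,
    multi-anchor hubs, loop-length statistics), core differentially expressed
    gene identification by N-way intersection of pairwise comparisons,
    transcription-factor network inference (PWM scanning, motif enrichment in
    gained regions, target assignment near transcription start sites,
    motif-pair distance statistics), over-representation analysis, and a
    fully deterministic synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
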