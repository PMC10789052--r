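Package: polpool
Title: Pol II Pool-Size Genomics: Occupancy, Anchored Differential
    Expression, Variant Prioritization, and Incidence Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studies of RNA polymerase II (Pol II)
    pool-size homeostasis and its phenotypic consequences. Provides
    strand-aware genomic region schemes around transcription start and end
    sites, ChIP-seq fragment counting, FPKM and pausing-index computation,
    metagene and TSS-centred profiles, TMM/voom-based differential Pol II
    occupancy testing, transcript-level differential expression with a Pol
    III-transcribed anchor gene (Rn7sk-style) normalization, a rare-variant
    prioritization cascade with CADD-Phred percentile arithmetic and Fisher
    exact case-control association, Mendelian segregation and
    embryonic-lethality accounting for mouse crosses, and AP-MS
    spectral-count interactor scoring. Seeded synthetic-data generators
    emulate every input with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    limma,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
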