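Package: bindscape
Title: Binding-Region Landscapes Across Gene Structure and Chromatin States
Version: 0.1.0
Authors@R: person("bindscape", "maintainers", email = "bindscape@example.org",
    role = c("aut", "cre"))
Description: Analysis of transcription-factor binding regions (ChIP-Seq peaks)
    relative to gene structure and chromatin states. Provides peak-height
    filtering, location classification (TSS / GENE / INTERGENIC), Monte-Carlo
    genome-track permutation tests, TSS-relative occurrence profiles with an
    explicit bimodal (background + two Gaussians) model, chromatin-state
    stratification, strand-aware upstream-region dataset construction,
    position-weight-matrix scanning with min-max normalized scores,
    Fisher-exact / EASE-score GO-term comparison between two gene lists, and a
    seeded synthetic-data generator (genome, annotation, nine-state chromatin
    map, peaks, planted motifs, GO annotations) so the whole pipeline runs and
    is validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
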