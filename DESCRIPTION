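Package: aluedit
Title: Genomic Architecture and Editability of Alu Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies A-to-I RNA editability of Alu repeat elements from
    site-level read counts and models its dependence on genomic architecture.
    Reads repeat annotations (RepeatMasker, UCSC rmsk, BED) and gene models
    (refFlat, BED12), restricts Alu elements to genic context, aggregates
    per-adenosine A/G read counts into a per-element editability statistic
    with coverage filters, and derives architecture covariates: distance to
    the nearest reversely oriented Alu, windowed same-strand and
    reverse-strand neighbor counts, intron/exon co-residence, pair sequence
    identity, and subfamily relations. Fits an exponential distance-decay
    model of editability with residual neighbor-count regression and
    variance decomposition, including strand-stratified fits. A calibrated
    synthetic-cohort generator reproduces the statistical structure of
    genome-wide editability surveys so that every pipeline stage can be
    tested without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
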