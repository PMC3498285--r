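Package: tilereg
Title: Dissection of an ECF Sigma-Factor Regulon from Tiling-Array Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines an extracytoplasmic-function (ECF) sigma-factor regulon from
    strand-specific tiling-array transcriptomes of a wild-type strain and
    regulatory mutants. Probe-level signals are smoothed by a running median and
    aggregated per annotated feature, quantile-normalized, and fitted with a
    per-feature one-factor genotype model; empirical false-discovery rates
    (global and subset-restricted) are estimated from the p-value ensemble.
    Condition-dependent expression profiles are clustered by correlation with a
    fixed cutoff and scored for stress-specific induction, and a deterministic
    rule cascade partitions genes into core, secondary, read-through and
    background regulon calls with operon-composition summaries. A synthetic-data
    generator emulating the genotype-by-replicate tiling design makes every
    stage testable without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
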