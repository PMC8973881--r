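Package: ipdkin
Title: Separating DNA-Modification Signals from Sequence-Context Polymerase
    Kinetics in Single-Molecule Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing interpulse durations (IPDs) from
    single-molecule real-time (SMRT) sequencing and for deciding whether a
    kinetic signal reflects a covalent base modification or an intrinsic,
    sequence-context effect on DNA polymerase speed. Provides a calibrated
    synthetic kinetics generator with planted modified motifs, per-site
    aggregation with robust outlier trimming and coverage filtering, IUPAC
    motif scanning and per-position IPD profiling, native versus
    whole-genome-amplified (WGA) comparison with rank-sum testing, extreme-IPD
    locus detection with window export for motif discovery, genomic-feature
    enrichment via two-sided binomial tests, and concordance statistics
    (Pearson r, R squared, RMSE) for replicate and model-predicted kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
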