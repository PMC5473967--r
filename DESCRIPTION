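Package: dualtrans
Title: Dual-Organ Around-the-Clock Translatome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification and comparative analysis of translation around the
    24-h day from paired ribosome-profiling (RPF-seq) and RNA-seq time series
    in two organs. Implements upper-quartile normalization, RPKM and
    translation-efficiency (TE) calculation, replicate measurement-error
    estimation, differential-TE testing with a fold gate, cross-organ
    translational-compensation statistics, harmonic rhythm detection by AIC
    model selection with an amplitude gate, phase-lag and cross-correlation
    analysis, circular phase statistics, AUG-initiated uORF detection and
    translation calling from A-site frame bias, Hellinger-distance isoform
    divergence, Kozak-context scoring, and profile-based hierarchical
    clustering. Ships a negative-binomial synthetic-data generator emulating a
    2 organ x 2 assay x 12 timepoint x 2 replicate design with known ground
    truth, so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
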