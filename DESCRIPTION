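Package: cnscope
Title: Multi-Resolution Copy-Number Tracks, Robust Reference Estimation
    and Static Review Plots for Clinical CNV Assessment
Version: 0.1.0
Authors@R:
    person("cnscope", "developers", email = "cnscope@example.org",
           role = c("aut", "cre"))
Description: Builds and reads multi-resolution copy-number track tables
    (tab-separated text, catalogued by a single index table), estimates
    copy number against a robust median/MAD reference assembled from a
    cohort of samples, re-bins third-party caller output (SEG, bedGraph)
    to the four display scales used for clinical review (1 Mb, 50 kb,
    5 kb, bait), supports sample-versus-sample ratio mode, contextual
    blacklist/whitelist filtering, QC statistics, a synthetic-cohort
    simulator with planted CNVs, and deterministic static rendering of
    the three-panel multi-scale view.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
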