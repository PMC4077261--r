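Package: spikenorm
Title: Spike-In Control Based Normalization for miRNA Microarrays
Version: 0.1.0
Authors@R:
    person("spikenorm", "developers", email = "spikenorm@example.org",
           role = c("aut", "cre"))
Description: Multi-array, intensity-dependent normalization of miRNA
    microarray raw data calibrated on spike-in control probes (SCN), with
    explicit applicability checks and a MEDIAN fallback. Includes an
    ImaGene-dialect text importer, median probe-set summarization,
    median and quantile baseline normalizations, present/absent detection
    calls (Exiqon threshold rule and Wilcoxon rank-sum rule),
    coefficient-of-variation quality-control metrics, dose-response
    differential expression with empirical-Bayes moderated t-statistics,
    comparative-Ct RT-qPCR processing, a fully specified synthetic
    experiment simulator with ground truth for method verification, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma,
    yaml
Config/testthat/edition: 3
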