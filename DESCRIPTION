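Package: bsrtools
Title: Burst-Suppression EEG, Fiber-Photometry and Molecular Quantification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of anesthesia-induced EEG burst
    suppression (suppression events by an amplitude-duration rule, cumulative
    suppression time, burst suppression ratio, relative band power), fiber
    photometry delta-F/F quantification, qPCR 2^-ddCt and densitometry
    normalization, and the Shapiro-Wilk-gated group-comparison statistics used
    in rodent anesthesia studies. Includes a seeded synthetic-cohort generator
    (alternating-renewal burst/suppression EEG, photometry decline, lognormal
    emergence times) with ground truth for every estimator, EDF/TSV trace I/O,
    and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    nortest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
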