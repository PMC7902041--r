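Package: ocuqtl
Title: Ocular Compliance Estimation and QTL Mapping in Recombinant Inbred Panels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline from raw stepped-pressure ocular perfusion traces
    to a quantitative-trait-locus scan. Estimates per-step ocular compliance by
    the Volume Filling and Step Response methods, fits the empirical
    pressure-compliance law to obtain a reference compliance with uncertainty,
    normalizes by ocular volume, applies percentile/best-eye/IQR quality
    control, aggregates to strain means, computes heritability and the
    effective corneoscleral modulus, and maps the trait by Haley-Knott interval
    regression on recombinant inbred genotypes with permutation-based
    significance thresholds. A synthetic-data module generates perfusion traces
    and RI-panel genotypes with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
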