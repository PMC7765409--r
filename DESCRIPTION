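Package: steatoscreen
Title: High-Content Screening Analysis of ER-Stress-Induced Hepatic Steatosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis chain for image-based phenotypic screens of lipid
    accumulation in hepatocyte-like cells: per-cell lipid-droplet
    quantification from two-channel microscopy fields (nuclei segmentation,
    cytoplasm ring regions, spot detection), 384-well plate quality control
    (Z'-factor, robust Z', signal-to-background, percent CV), normalized
    percent-inhibition hit and cytotoxicity calling, four-parameter logistic
    dose-response fitting with IC50/pIC50 and selectivity triage, fingerprint
    based Ward clustering of confirmed hits with pXC50 target profiling, and
    delta-delta-Cq relative expression for qPCR follow-up. A seeded synthetic
    data module generates ground-truth-labeled fields, plates, dose series,
    compound sets and Cq tables so every stage is benchmarked against known
    truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr,
    ape,
    knitr
Config/testthat/edition: 3
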