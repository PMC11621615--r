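Package: mirnorm
Title: Reference MicroRNA Stability and Normalisation for RT-qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies stable reference microRNAs in RT-qPCR panel data and
    normalises target microRNA expression against them. Provides Cq
    preprocessing (interplate calibration, replicate aggregation,
    low-expression filtering, relative-quantity conversion), three stability
    algorithms (geNorm iterative M-value ranking, BestKeeper index
    correlation, NormFinder model-based variance decomposition with optional
    grouping), cross-algorithm consensus shortlisting, geometric-mean
    normalisation factors, genotype comparisons with Holm-Sidak correction,
    and a synthetic-data generator that emulates a two-genotype,
    multi-muscle, longitudinal canine muscular dystrophy study design so
    every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
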