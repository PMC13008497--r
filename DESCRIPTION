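Package: plasmabridge
Title: Serum-to-Plasma Bridging of Multiplexed Proteomic Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quality-controlled harmonization of serum and plasma proteomic
    datasets measured on aptamer-based multiplexed assays (relative
    fluorescence units). Derives per-protein linear scaling factors from
    matched serum-plasma sample pairs by ordinary least squares in log2
    space, screens proteins by rank-correlation concordance with
    Benjamini-Hochberg control, applies interquartile-range outlier rules
    for sample pairing, contamination and cross-cohort generalizability
    quality control, and validates bridging by agreement of downstream
    predictions and pair co-clustering. Includes a fully seeded synthetic
    paired-cohort generator with known ground truth so every pipeline
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
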