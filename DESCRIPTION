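Package: mimicmap
Title: Cross-Dataset Concordance of Cancer Cell-Line and Tumour Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how well cancer cell lines mimic the expression pattern of
    the corresponding human tumours, following the multi-dataset microarray
    workflow used in hepatocellular carcinoma cell-line studies: per-dataset
    empirical-Bayes moderated t differential expression (a GEO2R-equivalent
    engine), consensus gene selection across cell-line datasets, z-score-of-fold
    ranking across tumour datasets, concordance and discordance calling,
    metabolic-gene mimicry assignment between representative cell lines,
    proteomics overlay, and hypergeometric/EASE gene-set over-representation with
    Benjamini-Hochberg FDR. Includes a fully seeded synthetic-data generator with
    planted truth so every stage is testable offline, and a pipeline driver with
    a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
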