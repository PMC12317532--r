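Package: methfield
Title: Differential DNA Methylation and Epigenetic Biomarkers in Hereditary Colorectal Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A reusable workflow for genome-wide DNA methylation array
    analysis of hereditary colorectal tumors and paired normal mucosa:
    probe filtering and beta/M conversion, covariate-adjusted differential
    methylation with empirical-Bayes variance moderation, region calling by
    bandwidth clustering with Stouffer combination, GSEA-style promoter
    enrichment with leading-edge probes, per-sample epigenetic biomarker
    scores (LINE-1 hypomethylation, CGI-promoter hypermethylation, CIMP,
    MSI, tumor mutation burden), epigenetic-clock age prediction, and
    methylation-expression integration. Includes a seeded synthetic-data
    generator with a planted-effect truth registry for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
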