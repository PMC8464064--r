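Package: estroepi
Title: Epigenetic Remodelling Under Estrogen Deprivation and Re-Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for DNA-methylation, H3K27ac and transcriptional
    remodelling of breast-cancer cells under estradiol deprivation and
    re-stimulation. Calls differentially methylated positions from beta-value
    matrices with an M-value linear model, validates specificity by
    treatment-label permutation, computes genomic-context annotation and
    differential/expected overlap fold-enrichment with Fisher exact
    significance, filters replicate ChIP peaks and calls differential H3K27ac
    binding, performs negative-binomial differential expression, classifies the
    reversibility of deprivation-induced changes after re-stimulation, and
    implements ChIP-qPCR percent-input, delta-delta-Ct and oxidative-bisulfite
    5hmC quantification. Ships a synthetic-data generator emulating the
    two-treatment multi-timepoint replicate design so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
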