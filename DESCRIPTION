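Package: methmark
Title: Discovery and Evaluation of Promoter Hypermethylation Biomarkers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for discovering and evaluating promoter
    CpG-island hypermethylation biomarkers in cancer: a demethylating-drug
    (5-aza-2'-deoxycytidine) reactivation screen on expression matrices,
    promoter CpG-island detection, bisulfite clone-sequencing methylation
    quantification with bisulfite-aware alignment, array-cohort methylation
    scoring (two-probe averaging, min-max/logistic normalization,
    hypermethylation calling, diagnostic ROC), Kaplan-Meier relapse-free
    survival with a Gehan-Breslow-Wilcoxon cutoff scan, and qPCR/IHC
    quantification utilities. Synthetic-data generators emulate every input
    class so the full workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
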