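Package: ctxomics
Title: Cross-Omics Analysis of Cytotoxic T-Cell Differentiation Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for dissecting the transcriptional and
    epigenetic program of human cytotoxic CD4 T cells: subset-specific
    gene-set derivation by the min/max rule, permutation gene set
    enrichment analysis (weighted Kolmogorov-Smirnov statistic with
    gene-set permutation, NES and FDR), Infinium 450K-style differential
    methylation (beta/M-values, peak-based type-I/II correction, paired
    t-tests on M-values with delta-beta calls), promoter
    methylation-expression integration, and calculators for the
    accompanying bench assays (delta-delta-Cp qPCR, ChIP percent-input,
    cytotoxicity, single-cell co-expression, bisulphite pyrosequencing).
    Ships a seeded synthetic-data generator emulating a paired
    multi-donor T-cell subset study so the whole analysis is exercised
    end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
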