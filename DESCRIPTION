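Package: gclineage
Title: Copy-Number Lineage Analysis of Gastric Intramucosal Neoplasms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for risk stratification of gastric intramucosal
    neoplasms from array-CGH copy-number profiles. Converts probe-level
    tumour/reference log2 ratios into gene-level copy-number calls, clusters
    samples into stable/intermediate/unstable lineages by unsupervised
    hierarchical clustering (uncentred correlation distance, complete
    linkage) with a gene-size model-selection sweep, screens for genes with
    differential copy number between lineages (Welch t-test, Bonferroni),
    computes chromosome-arm penetrance profiles, and classifies mucin
    phenotypes (G/GI/I/N) from immunohistochemistry scores. Includes a
    synthetic cohort generator with known lineage structure so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mclust,
    IRanges,
    S4Vectors
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
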