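Package: gctomics
Title: Integrative miRNA, mRNA, Copy-Number and Survival Analysis of
    Pediatric CNS Germ Cell Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the integrative genomics of pediatric
    central nervous system germ-cell-tumor prognostic groups: differential
    miRNA signatures (Student's t with fold-change filtering) and mRNA
    signatures (empirical-Bayes moderated t with Storey positive-FDR
    q-values); embryonic-stem-cell proximity via the inter-group
    average-linkage Euclidean distance statistic; anti-correlated
    miRNA-target pairing with per-miRNA Fisher's exact enrichment;
    SNP-array copy-number calling from log-R ratio and B-allele frequency
    tracks with group-wise recurrent-region intersection and
    expression-signature integration; gene-set and cytoband
    over-representation; Kaplan-Meier and log-rank survival comparison.
    A synthetic-cohort generator with recorded ground truth emulates the
    study design so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
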