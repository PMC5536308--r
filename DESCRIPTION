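Package: silacseq
Title: Spike-In SILAC and Count-Based RNA-Seq Multi-Omics Comparison
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for comparing mutant and wild-type
    gene expression across a spike-in SILAC proteome and a count-based
    RNA-seq transcriptome. Implements ratio-of-ratio ("deconvoluted ratio")
    protein quantification with median scaling and one-sample t-tests,
    a negative-binomial exact test with TMM normalisation and
    Benjamini-Hochberg adjustment for transcript differential expression,
    permutation significance of Venn-region overlaps between per-condition
    significant sets, GO enrichment with the elim decorrelation algorithm
    and two-tailed Fisher's exact tests, and oogenic/spermatogenic
    gene-class distribution profiling. A synthetic-data module generates
    all pipeline inputs with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
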