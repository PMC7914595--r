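Package: sixvp
Title: Six-Variable Gene Expression Profiles for Trans-Omics Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes multi-source omics measurements of six gene expression
    variables (transcription rate, mRNA stability, mRNA abundance, translation
    rate per mRNA, protein stability and protein abundance), builds rank-based
    six-variable profiles (6VPs) for genes and gene groups, clusters genes by
    expression strategy with a self-organizing tree algorithm, tests Gene
    Ontology term enrichment with hypergeometric statistics and FDR control,
    quantifies profile proximity within protein complexes and functional
    categories, estimates each variable's contribution to protein abundance by
    Bayesian model averaging under a Zellner g-prior, and derives cross-organism
    phenograms from GO-term-level profiles via neighbor-joining and UPGMA. A
    synthetic-data generator produces ground-truth-labeled inputs with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
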