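Package: senescreen
Title: Analysis of Pro-Senescence Kinase Screens from RT-qPCR Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing functional kinase screens that read out
    cellular senescence by RT-qPCR. Converts raw cycle-threshold (Ct)
    tables into reference-normalized relative expression and fold changes
    versus an empty-vector control (delta-delta-Ct), performs staged hit
    calling (anti-proliferative, SASP-inducing, p16-inducing, and their
    intersection with Venn summaries), computes induction-profile
    analytics (min-max induction scaling, log2 matrices, Spearman
    correlation matrices with p-values, hierarchical clustering of genes
    by induction profile), and tests gene lists for over-representation
    in GMT gene-set collections using hypergeometric and EASE-score
    statistics with fold enrichment and Benjamini-Hochberg adjustment.
    Includes a synthetic screen generator with a latent NF-kB-like
    program so every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
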