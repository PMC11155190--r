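Package: methcobind
Title: DNA Methylation Patterns at Transcription Factor Binding Regions
    Across Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative epigenomics of CpG methylation at transcription
    factor binding regions (TFBRs). Builds length-normalized binding
    regions from replicated ChIP-seq peaks, anchors binding sites on the
    motif match closest to the peak summit, summarizes per-region CpG
    counts and methylation from whole-genome bisulfite sequencing
    coverage, classifies hyper- and hypomethylated regions against
    matched controls for transposable-element enrichment, clusters
    spatial methylation profiles with a binomial-probit radial basis
    function mixture, segments methylomes into unmethylated, lowly
    methylated and fully methylated regions, detects CpG islands, and
    classifies cross-species binding conservation by parsimony over a
    mammalian phylogeny, linking methylation profiles to binding gain
    and loss. Ships a multi-species synthetic data generator with
    planted ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
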