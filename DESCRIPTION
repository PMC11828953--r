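Package: c4omics
Title: Multi-Omics Statistics for the Regulation of C4 Photosynthesis Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcriptome (TPM), proteome (iBAQ) and ribosome
    profiling (RPF) abundance tables across species to compute protein-to-mRNA
    ratios and translation efficiency for gene sets, with mean +/- SD and
    extreme-fraction classification, Z-score normalization, log-scale
    correlation, and ANOVA-gated Wilcoxon gene-set comparisons with
    Benjamini-Hochberg correction and a resampling control. Tests enrichment
    of cis-regulatory elements among accessible-chromatin occurrences
    associated with a target gene set by Monte Carlo permutation and Fisher's
    exact test, with strand-aware genic/upstream/downstream context
    assignment. Provides sequence-level classifiers: third-codon-position GC
    content (GC3), an inverted-repeat plus target-site-duplication scanner for
    retroduplication signatures, and a functional-paralog rule based on
    transcript abundance. Refines gene regulatory networks by cognate
    cis-regulatory-element filtering and summarizes transcription-factor
    families. A synthetic multi-omics generator with recorded ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
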