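Package: vinekit
Title: Gene-Model Reconciliation, Expression Mining and In Silico
    Genotyping for Grapevine Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for haplotype-resolved grapevine genome and
    transcriptome analysis. Reconciles a query gene annotation against a
    reference model (liftover acceptance at 80/80 coverage/identity,
    nonsense-mediated-decay and reverse-transcriptase template-switch
    transcript filters, expression-support and pseudogene filters, and
    novel/covered/fused/split classification); normalizes RNA-seq counts
    to transcripts per million and mines them with correlation-based
    tools (correlation gene finder, clustered heatmaps, weighted
    correlation networks, expression profiles, 2^-ddCt qPCR math);
    annotates genes impacted by structural variants between haplotypes;
    performs in silico SNP-marker genotyping of assemblies with
    identity-by-state distances and neighbor-joining trees; and ships
    seeded synthetic-data generators with known ground truth for every
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
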