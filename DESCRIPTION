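Package: retroscape
Title: Retrotransposon Landscape, Age, Methylation, 3D-Genome and
    Expression Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for LINE and SINE retrotransposon landscapes
    in mammalian genomes. Provides readers for RepeatMasker annotation,
    GFF3 gene models, FASTA, binned Hi-C contact matrices and per-CpG
    methylation tables; windowed distribution statistics with
    Wald-Wolfowitz randomness testing and TE block detection; genic-context
    annotation with hypergeometric set enrichment; Kimura two-parameter
    divergence and insertion-age dating with divergence landscapes;
    GC-content and CpG-methylation association statistics; A/B compartment
    calling and TAD-separation boundary detection from contact matrices;
    and post-quantification TE expression analytics (TPM, expression
    filtering, polynomial time-course differential selection, silhouette
    clustering, TE-gene correlation links). A full set of synthetic-data
    generators with known ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    limma,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
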