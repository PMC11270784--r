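Package: niltriage
Title: Variant Triage and Candidate-Gene Prioritization for Near-Isogenic Line Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triaging whole-genome variants between a pair of
    near-isogenic lines (NILs) and prioritizing candidate genes for the
    differential trait. Implements tiered VCF filtering (read depth,
    quality-criterion counts, contrasting homozygosity, chromosome
    anchoring), classification of variants against a GFF3 gene annotation
    into intragenic region types (CDS, non-coding exon, intron, non-coding
    RNA classes), a minimal coding-effect classifier with protein-consequence
    prediction, residual-heterozygosity accounting under repeated selfing,
    Fisher exact GO-term enrichment, haplotype-group assignment with
    days-to-flowering comparisons across a germplasm panel, and FPKM-to-TPM
    conversion with complete-linkage hierarchical clustering of expression
    profiles. A synthetic-data module generates annotation, NIL VCF,
    pangenome and expression fixtures with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
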