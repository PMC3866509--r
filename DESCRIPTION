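Package: CompYeast
Title: Comparative Genomics and Transcriptomics of Compact Yeast Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of small, gene-dense yeast genomes:
    scaffold and genome composition accounting, sliding-window GC landscapes
    and AT-rich centromere-candidate detection, telomeric-repeat and
    subtelomere annotation, clustered LTR-like repeat discovery, genome
    self-search segmental-duplication estimation and protein-family
    redundancy, coverage-based tandem-repeat copy-number estimation,
    reciprocal-best-hit orthology with synteny-block chaining and gene-loss
    mapping, two-condition RNA-seq differential expression from mapped-read
    counts, and Fisher exact gene-set enrichment with Benjamini-Hochberg
    false-discovery-rate control. A synthetic-data module generates genomes,
    proteomes, count tables and coverage tracks with recorded ground truth so
    that every stage can be validated against planted features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Transcriptomics, ComparativeGenomics, Coverage,
    Alignment, GeneExpression
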