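Package: parZ
Title: Pseudoautosomal Boundary Detection and Faster-Z Evolution Analysis
    for Avian Sex Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the evolution of partially differentiated
    avian (ZW) sex chromosomes. Annotates pseudoautosomal (PAR) versus
    differentiated (DR) regions of a Z chromosome from windowed female read
    depth, male/female expression ratios and female heterozygous-SNP
    density; estimates chromosome-wide dN, dS and dN/dS as ratios of sums
    with bootstrap confidence intervals and permutation tests against
    size-matched autosomes (the faster-Z test); computes
    efficacy-of-selection proxies (GC3s, effective number of codons with
    background correction, transposable-element and exon density, intron
    sizes); and quantifies dosage compensation and sex-biased-gene
    enrichment from RNA-seq counts. A seeded synthetic-data generator
    produces genomes, depth tracks, divergence tables, variants and
    expression counts with known ground truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    yaml,
    boot
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Sequencing, Coverage, GeneExpression
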