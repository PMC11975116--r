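Package: vntrspan
Title: Spanning-Read Coverage and Repeat-Count Genotyping QC for VNTRs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control for long-read genotyping of Variable Number
    Tandem Repeats (VNTRs). Curates a VNTR catalog from Tandem Repeats
    Finder or BED records with gene-proximity, repeat-element and
    segmental-duplication filters; counts spanning and reliable reads per
    locus per sample from SAM/BAM alignments; classifies per-locus coverage
    against a binomially derived minimum spanning-read threshold; scores
    consensus motifs for imperfect internal (STR-like) repeat structure
    with a circular masked-Hamming similarity; calls diploid repeat-count
    genotypes from reliable spanning reads with a minimum-support accuracy
    filter; and evaluates genotype concordance between read sets and
    Mendelian consistency in trios. A self-contained simulator generates
    reference contigs with planted VNTRs, diploid samples and trios, and
    HiFi-like read sets under targeted-capture (GC- and probe-distance
    dependent dropout) or unbiased whole-genome sampling models, with full
    ground truth.
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
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Coverage, Genetics, Sequencing, QualityControl
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'threshold.R'
    'strlike.R'
    'catalog.R'
    'coverage.R'
    'genotype.R'
    'simulate.R'
    'pipeline.R'
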