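Package: HierPhase
Title: Read-Based Diploid Haplotype Phasing by Confidence-Guided
    Hierarchical Assembly
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Read-based phasing of heterozygous bi-allelic SNPs from
    short-read sequencing data. Variants connected by haplotype-informative
    read pairs are partitioned into blocks and each block is phased by
    hierarchical agglomerative assembly: variant pairs are ranked by an
    adjusted multinomial confidence score and merged from the most to the
    least reliable pair, falling back to a local two-candidate minimum
    error correction (MEC) vote at interleaved merges or when only
    ambiguous pairs remain. Includes fragment extraction from BAM/VCF, a
    plain-text SNP-fragment matrix format, phased VCF output, the full
    switch/flip, phasing-error-rate, perfect-ratio, QAN50 and EC-rate
    evaluation metric suite, and a configurable diploid fragment simulator
    for benchmarking under varying coverage, sequencing error and
    haplotype sampling skew.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, VariantAnnotation
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'local-mec.R'
    'scoring.R'
    'assembly.R'
    'evaluation.R'
    'utils.R'
    'fragments-io.R'
    'simulate.R'
    'pipeline.R'
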