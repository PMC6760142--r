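Package: mutacolony
Title: Genome Characterization Toolkit for Transgenic Mouse Colonies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analyses for whole-genome characterization of transgenic rodent
    colonies such as the MutaMouse (lambda-gt10/lacZ) model: attribution of
    colony variants to parental inbred strains, CNV calling from binned read
    depth and aCGH probe ratios with cross-sample and cross-method consensus
    and simple/complex classification, constitutional-variant calling across
    a multi-copy tandem transgene array, reconstruction of the transgene
    integration junction from chimeric long reads, and colony-divergence
    statistics (homozygous-variant partitioning, genotype discordance, runs
    of homozygosity, neighbor-joining trees). A forward-time pedigree and
    genome simulator generates every input the pipeline consumes, so all
    stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, StructuralVariation, VariantAnnotation,
    Genetics, Sequencing
RoxygenNote: 7.3.3
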