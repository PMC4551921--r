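Package: indelCensus
Title: Estimating the Total Number of Small Indels in a Diploid Genome
    from Dual-Platform Sequencing Evidence
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the genome-wide number of small (1-10 bp)
    insertions and deletions from two complementary sequencing platforms: a
    high-coverage short-read platform and a low-coverage long-read platform.
    Implements allele-specific read classification on glued alternate
    contigs, zygosity calling with exact binomial misclassification
    probabilities, the fraction-of-informative-reads (FIR) diagnostic,
    greedy homopolymer/dimer tract annotation with indel density and
    residual-fraction metrics, a false-discovery and false-negative
    corrected estimator of the total indel count, and a sequential-mutation
    simulator showing how indels merge in homopolymer tracts over
    evolutionary time. A synthetic-data module generates diploid genomes
    with planted indel truth, platform read sets, and virtual call sets
    with known error rates so the full estimation chain can be validated
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Software, Sequencing, GenomicVariation, VariantDetection,
    Coverage, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
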