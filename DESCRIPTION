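Package: mosaic11p
Title: Detection and Quantification of Mosaic 11p15.5 Alterations in Liver Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies mosaic alterations of the imprinted 11p15.5
    locus (copy-neutral loss of heterozygosity, paternal duplication, IC1/IC2
    epimutations) in non-tumor tissue from four data modalities. Bulk SNP
    allele depths from matched non-tumor/tumor pairs are converted to B-allele
    frequencies, phased against the tumor, and summarised into a mosaic cell
    fraction with an exact binomial detection test. MS-MLPA probe and RRBS
    CpG methylation yield imprinting-center means, the IC1/IC2 ratio and a
    methylation-based mosaic fraction, with per-probe k-means classification
    of gain-of-methylation IC1 and loss-of-methylation IC2 epimutations.
    Single-nucleus allele counts at tumor-phased SNPs genotype individual
    nuclei for copy-neutral LOH, and splice-junction depths quantify adult
    versus fetal IGF2 promoter usage. A synthetic-data generator reproduces
    the statistical structure each stage assumes so the whole pipeline is
    testable without access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: CopyNumberVariation, DNAMethylation, Epigenetics, SingleCell,
    SNP, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
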