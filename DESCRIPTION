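Package: sweepscan
Title: Windowed Selective-Sweep Scans from Population Resequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting selective sweeps between a
    focal (e.g. highland) and a reference (lowland) population group from
    diploid biallelic SNP genotypes.  Includes a coalescent-style
    synthetic-data generator with planted hard-sweep footprints, paired-end
    FASTQ quality filtering, VCF site- and analysis-set filters, windowed
    population-genetic estimators (nucleotide diversity, Watterson's theta,
    Tajima's D, Hudson and Weir-Cockerham F_ST), joint top-quantile outlier
    detection with region merging and gene annotation, targeted-gene
    background contrasts, binomial gene-set enrichment with FDR control,
    neighbor-joining trees and genotype PCA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
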