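Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and LD Decay from SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in SNP-array genotypes with the
    sliding-window algorithm used by array-based livestock studies, classifies
    segments by length, computes the genomic inbreeding coefficients F_ROH (per
    length class and total) and F_HOM together with their Pearson correlations,
    locates ROH islands as merged runs of top-percentile per-SNP ROH incidence,
    and estimates linkage-disequilibrium decay (pairwise r-squared binned by
    physical distance). Reads and writes PLINK PED/MAP text and BED/BIM/FAM
    binary genotypes and applies standard call-rate/MAF/autosome quality
    control. A seeded synthetic-genotype generator plants autozygous tracts
    with known genome fraction, shared island regions and haplotype-block LD so
    every stage of the analysis can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
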