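Package: herdgen
Title: Genomic Diversity, Family Structure, and Inbreeding Assessment for
    Conserved Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the conservation status of closed livestock
    herds from SNP-array genotypes. Reads and writes PLINK 1 text and binary
    genotype files; applies marker quality control (call rate, minor allele
    frequency, exact Hardy-Weinberg test, autosome restriction) and computes
    diversity statistics (polymorphic marker ratio, expected and observed
    heterozygosity); estimates effective population size from binned linkage
    disequilibrium via the Sved equation; builds VanRaden genomic relationship
    and identity-by-state distance matrices; clusters sires into familial
    lineages with neighbor joining and assigns dams to families by genomic
    relationship; detects runs of homozygosity with sliding-window criteria
    and derives the genomic inbreeding coefficient F_ROH. A pedigree
    gene-dropping simulator with exact identity-by-descent tracking provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
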