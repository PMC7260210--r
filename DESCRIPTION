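Package: subpopscan
Title: Genomic Characterization and Selection-Signature Scanning for Paired
    Subpopulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize two geographically separated subpopulations
    of a livestock breed from SNP genotypes and to scan their genomes for
    selection signatures. Implements VanRaden method-1 genomic relationship
    matrices with a fixed base allele frequency, genomic inbreeding from the
    GRM diagonal and from runs of homozygosity (ROH), PLINK-style sliding
    window and consecutive-run ROH detection with island calling,
    haplotype-based linkage-disequilibrium decay and cross-population
    persistence of phase, the varLD ranked-eigenvalue contrast of regional LD,
    per-SNP and windowed Weir-Cockerham F_ST with heterozygosity-binned
    outlier calling, and consensus selection-signature reporting. A seeded
    two-population Wright-Fisher forward simulator with recombination,
    plantable divergently selected loci and plantable autozygous segments
    provides fully synthetic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
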