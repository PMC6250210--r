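Package: admixscan
Title: Coalescent Calibration and Genome Scans for Admixture between
    Cryptic Sympatric Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assess genomic admixture between closely related,
    sympatric species from whole-genome genotype data. A structured
    coalescent simulator with directional admixture pulses (sequentially
    Markovian recombination, HKY sequence evolution) calibrates the
    sensitivity of three complementary detectors: the three-population
    f3 statistic with block-jackknife standard errors, windowed
    population-genetic statistics (nucleotide diversity, absolute
    divergence dXY, Weir-Cockerham FST, Tajima's D), and a quartet
    tree-tip patristic distance proportion with tail-symmetry analysis.
    Includes VCF and FASTA import/export with depth and missingness
    filtering, window ranking for divergence scans, and an end-to-end
    simulation study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    ape,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
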