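Package: admixscan
Title: Introgression Scans, Pulse-Admixture Local Ancestry and Selection
    Statistics for Resequenced Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Frequency-based ABBA-BABA statistics (Patterson's D with
    block-resampled standard errors, windowed f_d), a single-pulse
    two-ancestry hidden Markov model for local ancestry inference with
    joint estimation of admixture proportion and time, ancestry-tract
    calling and tract-length admixture dating, de-introgression masking,
    windowed Weir-Cockerham F_ST and nucleotide diversity, XP-EHH
    selection scans with region merging, LD-based recent effective
    population size trajectories with slope-change detection,
    neighbor-joining SNP phylogenies, and a synthetic admixed-cohort
    generator with ground-truth ancestry tracts for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    ape,
    vcfR,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
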