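Package: invadepop
Title: Population-Genomic Scans for Recently Introduced Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for population-genomic analysis of
    recently introduced (invasive) insect cohorts sequenced as
    individuals: genotype-, site- and individual-level quality control
    of multi-sample VCFs; coverage-based genetic sex assignment;
    detection of putative chromosomal inversions from long-range
    linkage disequilibrium; KING-robust kinship, inbreeding, PCA and
    Weir-Cockerham FST; missing-data-aware windowed diversity
    statistics (pi, Dxy, Tajima's D, relative depth); and haplotype-
    based selection scans (EHH/iHS) combined with a dispersion-based
    differentiation score calibrated by pseudo-observed data. A
    synthetic cohort generator with ground truth (structured
    populations, inversions, sweeps, pedigrees, an X chromosome and
    depth-dependent missingness) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
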