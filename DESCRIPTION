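Package: sweepverdict
Title: Forward Simulation and Classification of Soft and Hard Selective Sweeps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how selective sweeps are defined and detected.
    Provides a single-site Wright-Fisher simulator of competing beneficial
    nucleotides under semidominant selection with recurrent mutation,
    frequency-threshold classifiers that distinguish sweep and soft-sweep
    calls from their eventual single- or multi-nucleotide outcomes, a
    deterministic selection-mutation trajectory model with establishment
    thresholds, a forward simulator of Drosophila-like 100-kb genomic
    elements (exon/intron architecture, discretized deleterious DFE,
    heterogeneous recombination maps, non-equilibrium multi-deme demography,
    Q-fold rescaling), haplotype-homozygosity statistics (H1, H2, H12,
    H2/H1) in SNP-count sliding windows, and synthetic-data generators
    including a neutral coalescent oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
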