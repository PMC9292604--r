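Package: ChelonScan
Title: Genome-Scale Hybridization and Demographic History Inference for Sea
    Turtles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing divergence, ancient gene flow and
    effective population size histories from small panels of whole genomes,
    motivated by the five globally distributed sea turtle species. Implements
    GATK-style variant hard filtering with callable-mask construction,
    windowed heterozygosity and identity-by-state distances, Patterson's D
    (ABBA-BABA) with weighted block jackknife, exact topology weighting of
    window gene trees over all rooted species topologies, a PSMC'-style
    discretized coalescent hidden Markov model fitted by EM for effective
    size trajectories, and hPSMC pseudo-F1 bracketing of the end of
    interspecific gene flow against clean-split simulation grids. A bundled
    coalescent simulator (backed by msprime) generates multi-species diploid
    genomes under isolation-with-migration demographies together with
    ground-truth records, so every stage of the pipeline can be validated on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    ape,
    phangorn,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
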