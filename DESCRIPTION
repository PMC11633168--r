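Package: urobiome
Title: Urinary Microbiome Profiling: Decontamination, Urotyping, Host
    Factors and Metagenome Genome-Wide Association
Version: 0.1.0
Authors@R:
    person("Urobiome", "Developers", email = "urobiome@example.org",
           role = c("aut", "cre"))
Description: An analysis toolkit for low-biomass (urinary) shotgun
    metagenomic profiles. Implements mock-control-aware three-step
    decontamination with a frequency-vs-DNA-concentration contaminant
    test, community diversity and ordination (Shannon/Simpson,
    Bray-Curtis, root Jensen-Shannon divergence, PCoA, PERMANOVA),
    urotype discovery by PAM clustering with Calinski-Harabasz model
    selection and LDA effect-size marker ranking, host-factor variance
    decomposition by distance-based redundancy analysis with variation
    partitioning, random-forest sex classification, and a dual
    linear/logistic metagenome genome-wide association scan with
    gene-environment interaction tests. Ships a synthetic-cohort
    generator with ground-truth bookkeeping so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
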