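Package: agefc
Title: Age-Dependent Resting-State Functional Connectivity of a
    Visual-Attention/Sensorimotor Seed Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage analysis of age-dependent resting-state functional
    connectivity (RS-FC) within a nine-node visual-attention/sensorimotor
    seed network. Stage one defines task-general regions by coordinate-based
    meta-analysis: nearest-experiment selection around each seed, activation
    likelihood estimation (ALE) with a random-spatial-association null,
    cluster-level family-wise-error correction by foci-relocation
    permutation, and a minimum-statistic conjunction across seed
    co-activation maps. Stage two estimates seed-network RS-FC per subject
    (nuisance regression with a 31-column first/second-order confound
    design, 0.01-0.08 Hz band-pass, 5-mm spherical seeds summarised by their
    first eigenvariate, pairwise Pearson correlation with Fisher-Z
    transform) and tests group-level connectivity and age effects (one-sample
    t-tests, Spearman rank correlation with age, Benjamini-Hochberg false
    discovery rate, 100-youngest vs 100-oldest extreme-group contrasts and
    change-pattern classification). A synthetic-data module generates
    multi-site BOLD cohorts with known age-dependent coupling, planted
    motion/drift/physiological confounds, and foci databases with planted
    convergence zones, so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: FunctionalConnectivity, fMRI, StatisticalMethod
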