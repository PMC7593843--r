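Package: dsaeselect
Title: Minority-Class SNP Selection with Deep Sparse Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validates panels of candidate single nucleotide polymorphisms
    (SNPs) against imbalanced binary toxicity outcomes using deep sparse
    autoencoders trained on the majority ("healthy") class. Reconstruction
    errors on a held-out mixed test set are averaged per class over resampled
    replicates; SNPs whose class-mean reconstruction-error difference exceeds
    percentile thresholds of the difference distribution are flagged as
    characterising the minority class. Includes derivation of late-toxicity
    endpoints from longitudinal ordinal symptom grades, a seeded synthetic
    radiogenomic cohort generator (Hardy-Weinberg genotypes with one linkage
    block, additive-logistic outcomes, grade trajectories), a univariate
    logistic comparison arm with Bonferroni control, and an end-to-end
    configured pipeline with tabular reports and two-panel figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    tibble,
    jsonlite,
    yaml,
    ggplot2,
    patchwork
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
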