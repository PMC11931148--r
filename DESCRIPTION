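Package: brainquant
Title: Lesion-Aware Brain MRI Volumetry for Children with Unilateral Cerebral Palsy
Version: 0.1.0
Authors@R:
    person("Brainquant", "Developers", email = "brainquant@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a lesion-aware brain
    quantification pipeline for paediatric unilateral cerebral palsy: silver
    ground-truth label fusion from lesion-affected and lesion-filled
    segmentations, robust percentile-based intensity normalization, a small
    trainable 3D U-Net pair for structural and lesion segmentation, lesion-free
    regional volumetry with hemispheric asymmetry, Dice/HD95 and defect-severity
    evaluation, and the clinical correlation statistics (Spearman with bootstrap
    confidence intervals, Mann-Whitney U, Wilcoxon signed-rank, intraclass
    correlation). Ships a seeded synthetic brain-phantom generator with exact
    voxel ground truth so every stage is verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
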