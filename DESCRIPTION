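Package: mshbm
Title: Individual-Specific Cortical Network Parcellation and Language
    Lateralization from Resting-State Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual-specific resting-state cortical networks
    with a multi-session hierarchical Bayesian model (MS-HBM): per-vertex
    functional connectivity profiles are binarized to their strongest
    correlations, clustered on the unit hypersphere with a mixture of von
    Mises-Fisher distributions to obtain group-average networks, and refined
    per subject through a three-level von Mises-Fisher hierarchy with a
    Markov random field spatial prior. Includes leave-one-run-out
    connectional homogeneity and stimulation-evoked inhomogeneity
    evaluation, a hemispheric laterality index over language networks with
    ANOVA/ROC analysis of language dominance, and a synthetic multi-subject
    cohort generator with planted parcellations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
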