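Package: evtopo
Title: Electrical Neuroimaging of Evoked Potentials: Topographic
    Clustering, Consistency Testing and Distributed Source Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference-independent analysis pipeline for multichannel
    evoked potentials: global field power and topographic measures,
    atomize-and-agglomerate hierarchical clustering (AAHC) of scalp
    topographies with explained-variance map selection, single-subject
    template fitting, the topographic consistency test (TCT), a
    distributed linear inverse with local autoregressive (inverse
    square distance) regularization on a spherical head model, and
    permutation-based 2x2 repeated-measures ANOVA with spatial cluster
    thresholding. Includes a forward-model based generator of synthetic
    multi-subject factorial somatosensory evoked potential studies with
    known ground truth, plus questionnaire and movement-kinematics
    feature extraction, so every stage of the pipeline can be validated
    end to end without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
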