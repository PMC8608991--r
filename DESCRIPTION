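Package: dbsconn
Title: Deep Brain Stimulation Connectomics on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for centromedian-nucleus deep brain
    stimulation (DBS) connectomics: estimation of the volume of tissue
    activated (VTA) from quadripolar lead geometry and stimulation settings
    (analytic point-source and finite-difference field solvers with an
    electric-field activation threshold), VTA-seeded structural connectivity
    from whole-brain streamline tractograms, discriminative fibertract
    scoring of streamlines against clinical seizure outcomes, seed-based
    normative resting-state functional connectivity (Fisher z, group t-map),
    and repeated-measures outcome statistics with Tukey-Kramer post hocs.
    All stages are exercised end-to-end on a synthetic head phantom and a
    synthetic patient cohort with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
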