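Package: airwaydeform
Title: Branch-Wise Deformation of the Bronchial Tree During Lung Collapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how the bronchial tree deforms when a lung collapses,
    from paired 3D airway segmentation masks of the inflated and the deflated
    state. Extracts rooted centerline trees from binary masks by topological
    thinning, rigidly registers the collapsed tree to the inflated one on the
    carina and the contralateral main bronchus, fits per-branch least-squares
    vectors, and reports per-branch displacement vectors, per-view angular
    deformations (with ancestor contributions subtracted so every branch's
    deformation is its own), length and maximal-diameter changes, and
    parenchymal volumes. A forward model applies a measured deformation table
    back onto an inflated centerline to synthesize an artificially collapsed
    bronchial tree, and a seeded phantom generator produces ground-truth
    airway trees and masks so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
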