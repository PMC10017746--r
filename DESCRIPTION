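Package: taunet
Title: Individualized Tau-PET Brain Networks from Template-Space SUVR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs per-subject weighted undirected brain networks from
    template-space tau-PET SUVR images. Network nodes are 3x3x3 cubes of 2-mm
    voxels placed at atlas-region centers and filtered by gray-matter coverage
    and pairwise independence; edge weights are absolute differences of node
    mean SUVR. Provides graph measures on the inverse-weight distance
    (nodal/global/limbic strength, weighted global efficiency via shortest
    paths), fixed-threshold and conditional-inference-tree tau staging,
    the accompanying statistical battery (ANCOVA Cohen's f with noncentral-F
    confidence intervals, Spearman correlations, Steiger's test for dependent
    correlations, chi-square contingency tests, ROC/AUC), and a synthetic
    phantom generator with Braak-like graded regional tau accumulation so the
    whole pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
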