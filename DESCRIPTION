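Package: kinesia
Title: Behavior and Whole-Brain Activity Analysis for Larval Zebrafish
    Catecholamine-Ablation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline linking catecholamine-ablation-induced locomotor
    impairment to brain-wide neural hyperactivity in larval zebrafish.
    Provides open-field tracking and locomotor metrics with an
    arena-exploration impairment classifier, tail kinematics and
    swim/flip/struggle event classification against a noise-floor unit,
    calcium-trace curation with constrained AR1 spike deconvolution and
    firing-rate estimation, cube-overlap assignment of neurons to atlas
    region masks, voxelwise and region-level two-group comparison with a
    Relevance score, hierarchical motor-associated clustering of neural
    activity with the tail trace, and region-pair connectivity. A
    synthetic-data module generates every input with planted ground truth
    so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
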