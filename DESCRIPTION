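Package: ededock
Title: Essential Dynamics Ensemble Docking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects a small set of representative receptor conformations
    from a molecular dynamics trajectory by principal component analysis and
    K-means clustering of binding-pocket features, and combines
    per-conformation docking scores into a single thermodynamically weighted
    ensemble binding score for virtual-screening triage. Includes a
    synthetic-data generator for multi-state pocket trajectories and
    docking-score tables with known ground truth, plus a resumable pipeline
    front end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
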