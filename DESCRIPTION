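Package: micelletools
Title: Trajectory Analysis of Block-Copolymer Micelle Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stages for molecular-dynamics trajectories of amphiphilic
    block-copolymer micelles: polymer-topology models (diblock, triblock and
    ring architectures with chemically-equivalent monomer classes), readers and
    writers for GRO/PDB structures and DCD/multi-frame text trajectories,
    single-linkage aggregate identification with periodic boundary handling,
    aggregation-number distributions and burn-in detection, gyration-tensor
    shape metrics, component-resolved radial density profiles, core
    composition and hydration-shell coordination statistics, an intrinsic
    core-shell interface construction with intrinsic density profiles, and a
    two-step conformational-landscape protocol (neighbor-graph nonlinear
    embedding followed by hierarchical density-based clustering). Includes a
    synthetic micelle generator with planted ground truth for validation, and
    a config-driven pipeline runner with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Matrix,
    igraph,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
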