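Package: groovescope
Title: Trajectory Analysis of Chaperone-Bound Tail-Anchored Helices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    carrier-protein dimers (Get3/TRC40/ArsA family) bound to a single
    tail-anchored transmembrane helix. Provides a helical-rotation metric
    about the ligand axis, terminal hydration-shell counting, residue to
    induced-pocket contact series, 2-D population binning with cluster and
    dwell-time extraction, per-cluster average structures, a pairwise
    generalized-Born/Lennard-Jones interaction-enthalpy surrogate, and
    analysis of NADH-coupled ATPase assay traces (initial rates, specific
    activities, relative Vmax tables). Includes a synthetic trajectory and
    assay generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
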