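Package: stereonav
Title: Camera-Guided Electrode Navigation: Geometry, Registration and
    Targeting-Accuracy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frameless, camera-guided stereotactic electrode
    navigation with a multi-guide-tube microdrive. Implements rigid
    paired-point (orthogonal Procrustes) registration with iterative
    closest-point surface refinement, trajectory planning and the
    rotate-then-translate alignment workflow with live offset readouts,
    microdrive guide-tube coordinate corrections, electrolytic iron
    deposit mass by Faraday coulometry, a synthetic-experiment generator
    emulating egg-white phantom and in-vivo deposition protocols, and
    the targeting-accuracy evaluation (per-axis offsets, distance to the
    planned electrode axis, 3D deviation, angular error, per-guide
    grouping, and depth-offset correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
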