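Package: exotendon
Title: Musculoskeletal Simulation of Passive Exotendon Assistance for
    Harvesting Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates passive elastic exotendon assistance of the back
    muscles during repetitive oil-palm harvesting pulls. Provides a reduced
    upper-body musculoskeletal model with Hill-type muscle fascicles, a
    synthetic six-sensor orientation-session generator with known ground
    truth, zero-phase Butterworth preprocessing and pull segmentation,
    orientation-based inverse kinematics, recursive Newton-Euler inverse
    dynamics with external hand loads, static optimization of muscle
    redundancy with reserve actuators and a parallel elastic exotendon, and
    evaluation utilities (peak metrics, body-weight normalization, reduction
    percentages, resting-length/stiffness parameter sweeps, one-way ANOVA
    and Tukey-Kramer comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
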