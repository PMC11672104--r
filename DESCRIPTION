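Package: tncoupling
Title: Troponin Phosphorylation Coupling Analysis Across Simulation,
    Filament and Myocyte Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of phosphorylation coupling in cardiac troponin and
    its restoration ("recoupling") by small molecules, at three scales:
    molecular-dynamics trajectory metrics (TnC helix A/B interhelix angle,
    NcTnC-ITC hinge angle, interdomain distance, salt-bridge and
    ligand-contact occupancy), in vitro motility calcium-activation curves
    (four-parameter Hill fits, EC50 phosphorylation ratios and coupling
    calls), and cardiomyocyte shortening transients (amplitude, ttp90,
    ttb90 and the dobutamine lusitropy statistic). Includes seeded
    synthetic-data generators that plant known ground truth for every
    stage, so the full pipeline is testable without simulation or wet-lab
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
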