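Package: gridshift
Title: Grid-Like Code Analysis for Rotating Cognitive Reference Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for hexadirectional (grid-like)
    fMRI signals in tasks whose target configurations rotate at unsignaled
    state changes. Generates predictive-inference task schedules, simulated
    agent behavior and multi-run BOLD data with planted k-fold directional
    modulation; provides behavioral transfer statistics (normalized angular
    error, guessing nulls, multi-timescale regressions), quadrature-regressor
    GLMs with an F-to-Z hexagonal modulation test, grid-angle estimation with
    between-state (cognitive versus spatial) and within-state leave-one-run-out
    cross-validation, fold-symmetry controls, trial-wise grid-phase dynamics,
    and trial-by-trial representational similarity analysis with searchlight
    mapping and sign-flip cluster-extent permutation correction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
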