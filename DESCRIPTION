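Package: rehabsim
Title: Simulation and Analysis of Adaptive Virtual-Reality Upper-Limb
    Rehabilitation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational core of home-based virtual-reality
    stroke-rehabilitation trials with a gamified reaching and grasping task.
    Implements the adaptive difficulty controller that holds the per-limb
    success ratio inside a target band, automated kinematic evaluation of
    upper-limb motor function (zero-phase Butterworth filtering, reaching
    work area, finger flexion and extension descriptors), navigated
    brain-stimulation motor-map metrics (resting motor threshold,
    stimulation efficacy, amplitude-weighted map centroid, centroid
    displacement, map area), and the nonparametric statistical layer of a
    two-arm trial (Wilcoxon, Mann-Whitney, Friedman, Spearman, pooled
    Cohen's d, scale-polarity handling). A synthetic cohort generator with
    known ground truth emulates patients, trial logs, kinematic streams,
    stimulation maps and clinical score panels, so every stage is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
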