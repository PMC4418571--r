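Package: tonorep
Title: Tonotopic Parcellation and Repetition Suppression Analysis for
    Auditory fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses travelling-wave tonotopy and block-design
    repetition-suppression experiments in early-stage auditory cortex. Provides
    a synthetic-data generator for cortical sheets carrying two mirror-symmetric
    primary frequency gradients (A1 and R) plus a frequency-selective surround,
    lagged cross-correlation mapping of per-voxel best frequency,
    gradient-reversal parcellation of the suprathreshold patch into ten regions
    of interest per hemisphere, iterative acoustic matching of repetition and
    control stimulus sets, and slope-based segmentation of block-averaged BOLD
    time courses into rise, plateau and decay phases with per-frame paired
    contrasts, two-way repeated-measures ANOVA and extrema statistics.
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
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
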