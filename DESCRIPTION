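Package: gazecoda
Title: Compositional Analysis of Area-of-Interest Gaze Dwell Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing eye-tracking dwell times aggregated over
    Areas of Interest (AOIs) as compositional data. Provides the Aitchison
    geometry kernel (closure, perturbation, centred and isometric log-ratio
    transforms, Aitchison distance, variation matrix and total variance),
    readers and validators for AOI fixation-duration exports, task-level
    descriptive summaries and ternary coordinates, log-ratio principal
    component analysis and hierarchical clustering of observations and AOIs,
    compositional MANOVA with Pillai's trace, balanced-design task-effect
    estimation on clr coordinates, Gaussian (linear and quadratic)
    discriminant classification of tasks with stratified cross-validation,
    a seeded logistic-normal generator of synthetic AOI experiments, and a
    pipeline driver that runs the compositional and classical analysis
    tracks side by side.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
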