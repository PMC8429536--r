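Package: voinoise
Title: Volume-of-Interest Noise Measurement for Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures computed-tomography image noise as the standard deviation
    of Hounsfield units inside the tracheal air column, comparing the
    conventional 1-cm2 circular region of interest (ROI) against a spherical
    volume of interest (VOI) of equal radius. Provides airway lumen
    segmentation in a 61x61x61 voxel crop with morphological erosion for a
    ground-truth noise estimate, carina-ridge landmark detection, a
    deterministic 27-position jitter simulating repeated manual placement,
    containment-based exclusion bookkeeping, Bland-Altman agreement analysis
    with Levene and Wilcoxon signed-rank comparisons, and a synthetic
    bifurcating-airway phantom generator with known injected noise for
    validation at cohort scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
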