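Package: ivimhist
Title: Intravoxel Incoherent Motion Histogram Analysis of Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxelwise segmented (stepwise) biexponential intravoxel incoherent
    motion (IVIM) fitting of multi-b-value diffusion-weighted MRI, two-point
    apparent diffusion coefficient (ADC) mapping, whole-lesion first-order
    histogram feature extraction, and a nonparametric group-comparison and
    ROC/Youden diagnostic-performance layer. Includes a synthetic phantom and
    cohort generator with Rician magnitude noise so the full pipeline is
    testable end to end without patient data, and NIfTI/CSV/JSON input-output
    utilities for running the pipeline on real acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pROC,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
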