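Package: cbss
Title: CSF-Based Spatial Statistics for Low-b Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parcellates cerebrospinal-fluid (CSF) spaces using gray-matter
    landmarks, fits per-voxel pseudodiffusivity (IVIM D*) from low-b
    diffusion MRI by log-linear regression, summarizes it as median
    pseudodiffusivity (MPD) per sulcus, cistern and ventricle, fine-maps it
    along the ventricles in distance zones from the start of the third
    ventricle, and runs reproducibility, inter-regional correlation and
    covariate-adjusted association statistics with Benjamini-Hochberg
    control and Cauchy (ACAT) p-value combination. Ships a synthetic digital
    head phantom so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
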