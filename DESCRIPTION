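Package: pettbi
Title: Skeletal Tumor Burden Quantification from NaF PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes volumetric skeletal tumor-burden indices from
    co-registered NaF PET standardized-uptake-value (SUV) volumes and CT
    bone masks: Gaussian smoothing in physical units, SUV-threshold
    hotspot detection by 3D connected components, bone-overlap filtering,
    manual hotspot classification, and the normalized PET/CT index
    (100 x 0.33 x hotspot volume / segmented bone volume) in both a
    manual-threshold and a fully automated SUV-15 variant. Includes the
    biomarker-evaluation statistics used to validate such indices
    (Kaplan-Meier with median-split groups, log-rank, univariate Cox,
    Harrell's concordance index with bootstrap confidence intervals and a
    paired comparison test, Bland-Altman agreement), plus synthetic
    phantom and survival-cohort generators with analytic ground truth,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    survival,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
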