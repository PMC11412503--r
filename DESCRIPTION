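Package: musclet2
Title: T2-Distribution Biomarkers for Muscle MRI in Dystrophic Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated analysis of multi-echo spin-echo MRI for grading
    muscle-disease severity in dystrophic (mdx) mice. Provides a synthetic
    multi-echo hindlimb phantom generator with known ground truth, NIfTI
    stack and mask handling, voxelwise monoexponential T2 fitting, T2
    histogram-shape biomarkers (interdecile range, kernel-density mode,
    Pearson mode skewness, D'Agostino K-squared normality test), and cohort
    statistics (Bland-Altman test-retest repeatability with minimum
    detectable change, dye-uptake regression, severity stratification and
    group balancing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
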