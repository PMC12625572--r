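Package: safemargin
Title: Safe-Margin Volume Generation for Computer-Assisted Bone Tumor
    Resection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates patient-specific safe-margin volumes for
    computer-assisted bone tumor resection from co-registered binary bone
    and tumor masks on anisotropic voxel grids. The tumor is extended
    uniformly by a prescribed safe margin (in millimetres) along the bone
    by fusing a coarse solution from an exact anisotropic Euclidean
    distance transform on the original grid with a fine "dangerous ring"
    computed on an odd-integer-replicated fine grid. Includes a
    morphological-dilation baseline, a brute-force point-cloud oracle,
    deterministic sphere phantoms with analytic ground truth, geometric
    error evaluation with confidence intervals, cross-method statistics
    (Anderson-Darling, Wilcoxon rank-sum), and Kaplan-Meier survival
    estimation, plus NRRD/NIfTI mask input and PLY/CSV/STL/NRRD output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RANN,
    survival,
    nortest,
    jsonlite,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    withr
Config/testthat/edition: 3
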