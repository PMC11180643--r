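Package: radagree
Title: Radiomic Feature Extraction and Cross-Software/Cross-Modality
    Agreement Analysis on Synthetic Tumor Phantoms
Version: 0.1.0
Authors@R:
    person("radagree", "developers", email = "radagree@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for extracting 66 IBSI-style radiomic
    features (shape, histogram, GLCM, GLRLM, GLZLM, NGTDM) from 3-D
    volumes with binary tumor masks under three voxel-resampling
    strategies and two configurable extraction dialects, and for
    quantifying feature agreement with the two-way mixed-effects
    absolute-agreement single-measurement intraclass correlation
    coefficient, banded as poor/moderate/good/excellent. Includes a
    synthetic paired CT/MRI phantom cohort generator with shared tumor
    geometry and tunable cross-modality texture correlation, minimal
    NIfTI-1 input/output, cubic B-spline resampling, fixed-bin-number
    discretization, and histogram-matching intensity normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
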