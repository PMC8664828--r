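Package: skelrad
Title: Skeletal PET/CT Radiomics for Bone Marrow Involvement Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end skeletal radiomics pipeline for assessing bone marrow
    involvement in lymphoma from baseline FDG PET/CT. Segments a skeleton
    volume of interest from CT by Hounsfield thresholding with per-slice
    morphological closing and hole filling, crops it to the axial analysis
    extent, excludes hip-prosthesis artefacts, and transfers the mask to the
    PET grid. Computes 26 conventional and textural PET features (grey-level
    co-occurrence, neighbourhood grey-level difference and grey-level
    size-zone matrices) under fixed absolute SUV discretization and spatial
    resampling. Builds a LASSO-selected linear prediction score (and ships a
    frozen published model), and evaluates diagnostic performance with ROC
    analysis, the Youden index, DeLong tests, Mann-Whitney, Fisher exact and
    Spearman statistics. Includes a seeded synthetic phantom generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
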