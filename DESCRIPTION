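Package: aletx
Title: Coordinate-Based Meta-Analysis and Imaging Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for linking task-fMRI coordinate-based meta-analysis to
    spatial gene expression. Implements activation likelihood estimation (ALE)
    with permutation-based voxel and cluster-level family-wise error control,
    meta-analytic connectivity modeling (MACM) against a coordinate database,
    term-based behavioral profiling of statistical maps, activation-gene
    expression association against a donor-wise expression atlas with
    random-effects combination, gene-list overlap statistics with
    similarity-constrained random-list and parcellation-restricted
    map-permutation nulls, hypergeometric gene-set overrepresentation with FDR
    control, and a synthetic-data module that generates every input with
    planted ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
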