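Package: UnifiedLSM
Title: Unified Level Set Segmentation of Liver and Liver Tumors in 2D CT Slices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semiautomatic segmentation of the liver and of liver tumors on
    single CT slices with a unified distance-regularized level set evolution
    (DRLSE) driven by both edge information (a geodesic edge indicator) and
    region information (a signed pressure force built from Chan-Vese region
    means). Liver segmentation combines anisotropic-diffusion/gradient/sigmoid
    preprocessing, seeded region growing on the binarized result, and level
    set refinement. Tumor segmentation restricts work to a rectangular ROI and
    builds an enhanced edge indicator from a local-intensity-clustering level
    set with multiplicative bias-field estimation followed by hidden Markov
    random field EM relabeling. Includes synthetic phantom generators, the
    five standard volumetric and surface-distance evaluation measures with
    challenge-style scoring, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, png, tiff, RNifti, jsonlite, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Segmentation, Visualization
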