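Package: petlymph
Title: Automatic Segmentation and Classification of FDG-PET Uptake Volumes in Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automatic pipeline that segments high-uptake volumes in
    whole-body FDG-PET scans of lymphoma patients and classifies each volume
    into one of 14 tissue categories (tumor and 13 non-tumor classes).
    Stages: Gaussian denoising and SUV conversion, a heuristic z-axis
    cropping algorithm anchored at brain and urinary-bladder level,
    SUV-thresholded watershed segmentation with texture-similarity merging,
    a 31-feature radiomics extractor (SUV statistics, NGTDM texture, shape
    and spatial location), and a random-forest classifier evaluated by
    nested cross-validation. A synthetic whole-body PET phantom generator
    with ground-truth labels makes every stage testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
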