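Package: otoct
Title: Denoising and Automatic Segmentation of Contrast-Enhanced Micro-CT
    Volumes of the Inner Ear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge-preserving noise reduction and automatic mask-based
    segmentation for osmium-tetroxide contrast-enhanced micro-CT volumes of
    the human inner ear. Implements a 2D-visualization denoising chain
    (per-slice histogram matching, iterated guided and bilateral filtering,
    unsharp masking) and a 3D-visualization chain (guided filtering, white
    top-hat extraction of bright neural structures with a large cross
    structuring element, binarization, geodesic opening of the mask,
    morphological closing and dilation, masked multiplication), all as fully
    3D operators with van Herk/Gil-Werman line-decomposed morphology.
    Includes reading/writing of TIFF stacks, NRRD and NIfTI-1 volumes, a
    seeded synthetic cochlear phantom generator with voxel-level ground
    truth, segmentation/noise metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
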