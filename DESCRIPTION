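Package: frustule3d
Title: Multiscale 3D Porosity Quantification for Diatom Frustule Volumes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the hierarchical porosity of Coscinodiscus sp. diatom
    frustules from tomographic voxel volumes. Provides bimodal thresholding,
    morphological cleanup and distance-transform watershed separation of pore
    space; global, per-layer and per-pore porosity metrics including pore
    volume distributions and chamber metrology; Minkowski-functional shape
    classification (planarity/filamentarity); chord-length distributions and
    specific-surface estimation; and projection-based 2D spectral (Porod)
    anisotropy analysis. Ships synthetic volume generators (geometric
    primitives, ellipsoidal nanopore fields, three-layer frustule units) with
    exact ground truth for parameter-recovery testing, plus TIFF/MRC/raw
    volume input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
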