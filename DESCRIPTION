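Package: cbctvol
Title: Serial CBCT Volumetry of Grafted Alveolar Ridges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional radiographic evaluation of customized bone-block
    grafts from serial cone-beam CT. Seeded region-growing and watershed
    segmentation, rigid intensity-based registration, logical-operator
    subtraction of segmented models, and volumetric/morphological stability
    metrics (new hard-tissue volume, T3/T2 ratio, Dice similarity coefficient,
    signed-surface-distance colormaps, linear ridge dimensions), together with
    a synthetic serial-CBCT ridge phantom generator with full ground truth and
    the nonparametric cohort statistics used in longitudinal graft studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
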