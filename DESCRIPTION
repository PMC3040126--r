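Package: ihcquant
Title: Automated Quantification of DAB/Haematoxylin Immunohistochemistry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies brightfield immunohistochemistry (IHC) spot images,
    such as Ki-67 stained tissue-microarray cores, by colour deconvolution
    of the haematoxylin and DAB stains in optical-density space, fixed
    thresholding of the unmixed channels, and computation of the extent
    (DAB-positive share of the stained area) and intensity of staining per
    spot. Includes patient-level aggregation with tertile or matched
    proportion grouping, linearly weighted kappa agreement statistics
    against visual scoring, a synthetic brightfield image generator with
    known ground truth for validation, and batch front-ends for whole
    directories of images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
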