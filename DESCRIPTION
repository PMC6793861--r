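Package: patrans
Title: Linear Multivariate Pattern Transformations Between Brain Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates linear voxel-by-voxel transformations between the
    multivariate activity patterns of two regions of interest using ridge
    regression with the regularisation parameter selected by
    leave-one-stimulus-out cross-validation (hat-matrix shortcut), and
    characterises the estimated mappings with three connectivity metrics:
    a cross-validated percentage goodness-of-fit, a Monte-Carlo-calibrated
    sparsity estimate based on the decay of the thresholded-density curve,
    and a pattern-deformation estimate based on the decay of the singular
    value spectrum. Includes synthetic generators for coupled region pairs,
    permutation testing of goodness-of-fit, representational dissimilarity
    analysis, and across-session metric averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
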