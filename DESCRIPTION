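Package: trajscore
Title: View-Invariant Movement Quality Scoring from Joint Trajectory Heatmaps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the quality of human movements (e.g. gait or sit-to-stand
    exercises in rehabilitation assessment) from 2D body-joint pose sequences in
    a camera-view-invariant way. Per-joint pose-probability heatmaps are stacked
    over short clips and collapsed by a learned temporal-aggregation convolution
    into trajectory descriptor maps; a spatial transformer with a 4-parameter
    affine sampling grid normalizes the descriptors across views; the stacked
    descriptors are classified into integer severity scores by an adapted
    image backbone. Includes a synthetic multi-view movement simulator with
    graded severity and occlusion, training and cross-subject/cross-view
    evaluation protocols with Spearman rank-correlation reporting, and a small
    command-line workbench. The network engine (convolution, pooling, bilinear
    sampling, backpropagation) is implemented natively in C++ and R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
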