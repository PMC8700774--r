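Package: visionqc
Title: Artificial-Vision Appearance Quality Monitoring for Fresh Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An artificial-vision pipeline for judging whether processed or
    stored food samples still look fresh. Generates synthetic imaging scenes
    with controllable degradation (surface whitening, color drift, texture
    change), standardizes colors against in-scene white and black references,
    segments the sample region of interest by k-means clustering, extracts a
    2576-dimensional appearance descriptor (color moments, multi-level wavelet
    texture statistics, gray-level co-occurrence matrices), and performs
    multivariate conformance testing with Hotelling's T-squared and Q-residual
    control charts built on a principal component model of fresh samples.
    Includes fractional-factorial study-design bookkeeping and a microbial
    log-reduction utility.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    EBImage,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
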