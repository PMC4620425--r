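Package: rocboost
Title: ROC-Space Boosting and Improved Haar-Like Features for Tongue Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an improved five-partition Haar-like rectangle feature
    for standardized 120x100 tongue images, integral-image based batch feature
    extraction, per-feature two-sample t-test screening, and ROC-Boosting: a
    feature-selection ensemble method that repeatedly picks the single-feature
    threshold classifier with the largest AUC deviation from chance, optionally
    constrained by a positive/negative ratio condition that guards against
    majority-class collapse under class imbalance, then removes the correctly
    classified examples and the selected feature and repeats. Includes a
    synthetic tongue-image generator with planted localized group differences
    for end-to-end testing, broom-style tidiers, ggplot2 visualizations, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
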