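Package: pipmorph
Title: Outline Morphometrics and Discriminant Classification of Grape Pip Silhouettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-image morphometrics for Vitis pips: converts scanned seed
    silhouettes into closed outlines, describes them with normalized elliptic
    Fourier descriptors (24 coefficients from the first six harmonics of
    360-point outlines), and classifies specimens by principal component
    analysis followed by stepwise linear discriminant analysis with
    leave-one-out cross-validation. Unknown specimens (e.g. fossil pips) are
    allocated to reference species groups by posterior probability, with an
    optional minimum-posterior threshold below which specimens are left
    unassigned. Includes a synthetic seed-shape generator with controlled
    class structure and a fossil-distortion model, so the whole pipeline is
    testable without proprietary seed images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    tiff,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
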