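Package: braingap
Title: Multilevel Grey-Matter Brain-Age Modelling and Brain-Age-Gap Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grey-matter-volume based brain-age analysis at global and
    regional (parcel) level: synthetic cohort simulation with recoverable ground
    truth, region-of-interest feature extraction from NIfTI volumes, support
    vector regression brain-age models with nested cross-validation,
    regression-to-the-mean bias correction and brain-age-gap (BAG) computation,
    covariate-adjusted group inference with false-discovery-rate control and
    ComBat harmonization, permutation-based canonical correlation analysis
    linking regional BAG patterns to clinical profiles, and meta-analytic
    functional decoding of affected regions against a labelled foci database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
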