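Package: cervicurve
Title: Quantify Cervical Spine Curvature and Model Its Population Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cervical sagittal alignment from a digitized
    anterior vertebral line. A polyline traced along the anterior margins of
    the cervical vertebral bodies is standardized to a chord-aligned
    coordinate frame, fitted with a second-order polynomial, and summarized
    by the curvature coefficient (the quadratic coefficient times 1000);
    curvature is classified as lordotic, straight or kyphotic via cutoffs
    calibrated to the Harrison posterior tangent global angle. Includes
    segmentation-agreement metrics (pixel accuracy, mean IoU, RMSE,
    ICC(2,1)), a synthetic cohort generator calibrated to published yearly
    means and class prevalences, and the trend-analysis stage: Wald
    prevalence intervals, per-stratum linear trends, multinomial logistic
    prevalence trends, and linear mixed-effects models with a per-subject
    random slope on year.
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
    lme4,
    lmerTest,
    nnet,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
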