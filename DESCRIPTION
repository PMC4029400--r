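Package: ctrss
Title: Case-Based Clinical Trial Recruitment Support from Routine EHR Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for case-based clinical trial recruitment
    support: entity-attribute-value (EAV) stored diagnosis and procedure
    codes are pivoted into sparse binary patient-by-attribute matrices at
    three hierarchical aggregation levels (original codes, category level,
    block level), attributes are reduced by documentation frequency or by
    chi-squared/Fisher association with trial eligibility, and five
    classifier families (CART trees, random forests, logistic regression
    with and without stepwise selection, support vector machines) are
    trained to score unscreened patients. Includes a holdout evaluation
    harness with ROC-AUC, bootstrap percentile confidence intervals,
    learning curves by iterative training-set reduction, a full experiment
    grid runner, and a synthetic EHR cohort generator with planted
    eligibility rules for end-to-end testing without hospital data.
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
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
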