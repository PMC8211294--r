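Package: gxeyield
Title: Genotype-by-Environment Soybean Yield Prediction with Recurrent
    Sequence Models and Temporal Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested pipeline for predicting multi-environment soybean seed
    yield from daily growing-season weather, maturity group and
    pedigree-derived genotype clusters.  Builds Wright's numerator
    relationship matrix from pedigree records by the tabular method,
    partitions genotypes by K-means on correlation profiles, downsamples
    daily weather to weekly/biweekly/monthly model time-steps, and fits two
    hand-authored many-to-one sequence regressors -- a stacked LSTM and a
    temporal soft-attention variant -- trained with Adam on mean squared
    error.  Includes greedy forward selection over weather variables,
    SVR-RBF and LASSO baselines, attention-profile interpretability
    summaries, and a synthetic multi-environment-trial generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
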