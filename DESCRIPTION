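Package: l2cforecast
Title: Longitudinal-to-Cross-Sectional Forecasting of Dementia Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms variable-length multimodal visit histories of ageing
    cohorts into fixed-length feature vectors (the L2C transformation) and
    trains multi-task forecasters -- a feedforward neural network and
    gradient-boosted trees with or without forecast-window stratification --
    to predict clinical diagnosis (CN/MCI/DEM), MMSE and ICV-normalised
    ventricle volume at arbitrary monthly horizons. Includes a synthetic
    longitudinal cohort simulator with sigmoidal biomarker trajectories,
    irregular visit schedules, per-modality missingness and site shift;
    participant-level cross-validation with a first-half/second-half
    evaluation protocol; pooled multiclass AUC and per-participant error
    metrics; and corrected resampled t-tests, permutation tests and
    Benjamini-Hochberg FDR control for model comparison.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
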