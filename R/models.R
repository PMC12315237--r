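# Forecaster bundles: windowed and non-windowed gradient-boosted trees, the
# multi-task network, the carry-forward baseline, and the CDR-to-diagnosis
# probability conversion.

TARGETS <- c("diagnosis", "mmse", "ventricle")

# xgboost's multiclass predict returns a matrix in recent versions and a
# row-major concatenated vector in older ones
softprob_matrix <- function(p) {
  if (is.matrix(p)) p else matrix(p, ncol = 3, byrow = TRUE)
}

#' Forecast-window specification for the windowed XGBoost variant
#'
#' Per-target ordered forecast-gap intervals in months: MMSE 0-9, 9-15,
#' 15-27, 27-39, >54; clinical diagnosis 0-8, 8-15, 15-27, 27-39, 39-60,
#' >60; ventricle volume 0-9, 9-15, 15-30, >30 -- fifteen (target, window)
#' models in total. The uncovered MMSE gap range (39, 54] routes to the
#' adjacent 27-39 model.
#'
#' @return An `l2c_windows` list of per-target interval tables.
#' @export
l2c_windows <- function() {
  mk <- function(lower, upper, label, closed_left = TRUE)
    tibble::tibble(lower = lower, upper = upper, label = label,
                   closed_left = closed_left)
  structure(list(
    # the ">54" MMSE window is strictly open on the left: (54, Inf); the
    # uncovered (39, 54] range routes to the 27-39 model in select_window()
    mmse = mk(c(0, 9, 15, 27, 54), c(9, 15, 27, 39, Inf),
              c("0-9", "9-15", "15-27", "27-39", ">54"),
              c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    diagnosis = mk(c(0, 8, 15, 27, 39, 60), c(8, 15, 27, 39, 60, Inf),
                   c("0-8", "8-15", "15-27", "27-39", "39-60", ">60")),
    ventricle = mk(c(0, 9, 15, 30), c(9, 15, 30, Inf),
                   c("0-9", "9-15", "15-30", ">30"))
  ), class = "l2c_windows")
}

#' Select the forecast window for a gap
#'
#' The gap is the time (months) between the forecast point and the most
#' recent observed measurement of the target variable. Intervals are closed
#' on the left, open on the right; MMSE gaps in the uncovered (39, 54] range
#' map to the 27-39 window. An undefined gap (target never observed) returns
#' `NA`: no model is selectable and the prediction is reported unavailable.
#'
#' @param gap_months Numeric gaps (>= 0; `NA` allowed).
#' @param target One of `"diagnosis"`, `"mmse"`, `"ventricle"`.
#' @param windows An [l2c_windows()] spec.
#' @return Integer window indices (NA where unavailable).
#' @export
select_window <- function(gap_months, target, windows = l2c_windows()) {
  target <- match.arg(target, TARGETS)
  if (any(!is.na(gap_months) & gap_months < 0)) stop("negative forecast gap")
  tab <- windows[[target]]
  out <- rep(NA_integer_, length(gap_months))
  for (i in seq_len(nrow(tab))) {
    above <- if (tab$closed_left[i]) gap_months >= tab$lower[i] else
      gap_months > tab$lower[i]
    hit <- !is.na(gap_months) & above & gap_months < tab$upper[i]
    out[hit & is.na(out)] <- i
  }
  if (target == "mmse") {
    hole <- !is.na(gap_months) & is.na(out) & gap_months > 39 & gap_months <= 54
    out[hole] <- 4L  # nearest lower boundary: the 27-39 model
  }
  out
}

#' Convert a predicted CDR score to diagnosis probabilities
#'
#' Anchors CDR 0 to CN, 0.5 to MCI and >= 1 to DEM, linearly interpolating
#' between anchors (CDR 0.1 gives 80% CN / 20% MCI; CDR 0.6 gives 80% MCI /
#' 20% DEM). Negative scores clip to 0. Probabilities sum to 1.
#'
#' @param cdr Numeric predicted CDR score(s).
#' @return Matrix with columns `p_cn`, `p_mci`, `p_dem`.
#' @export
cdr_to_diag_probs <- function(cdr) {
  stopifnot(all(is.finite(cdr)))
  cdr <- pmax(cdr, 0)
  p_cn <- pmax(1 - cdr / 0.5, 0)
  p_dem <- pmin(pmax((cdr - 0.5) / 0.5, 0), 1)
  p_mci <- 1 - p_cn - p_dem
  cbind(p_cn = p_cn, p_mci = p_mci, p_dem = p_dem)
}

# ---- feature matrices for the tree paths -------------------------------

# Trees consume all 70 features numerically: diagnosis categories as severity
# codes 0/1/2, sex and marital as 0/1, missing values passed through.
xgb_feature_matrix <- function(features) {
  out <- features[, l2c_feature_names()]
  for (col in c("mr_dx", "best_dx", "worst_dx")) {
    out[[col]] <- as.numeric(dx_severity(out[[col]]))
  }
  out$sex <- c(male = 0, female = 1)[out$sex]
  out$marital <- c(married = 0, not_married = 1)[out$marital]
  as.matrix(dplyr::mutate(out, dplyr::across(dplyr::everything(), as.numeric)))
}

#' XGBoost hyperparameters
#'
#' Defaults inside the documented search ranges (max depth 3-8, subsample
#' 0.4-1, learning rate 0.01-0.2).
#'
#' @param max_depth,subsample,eta Core tree parameters.
#' @param nrounds Boosting rounds.
#' @return A named list.
#' @export
xgb_params <- function(max_depth = 4, subsample = 0.8, eta = 0.1,
                       nrounds = 150) {
  stopifnot(max_depth >= 3, max_depth <= 8, subsample >= 0.4, subsample <= 1,
            eta >= 0.01, eta <= 0.2, nrounds >= 1)
  list(max_depth = max_depth, subsample = subsample, eta = eta,
       nrounds = nrounds)
}

fit_one_xgb <- function(X, y, target, params, seed) {
  keep <- !is.na(y)
  if (!any(keep)) return(NULL)
  set.seed(seed)
  if (target == "diagnosis") {
    dtrain <- xgboost::xgb.DMatrix(X[keep, , drop = FALSE], label = y[keep],
                                   missing = NA)
    xgboost::xgb.train(params = list(objective = "multi:softprob",
                                     num_class = 3,
                                     max_depth = params$max_depth,
                                     subsample = params$subsample,
                                     eta = params$eta, nthread = 1,
                                     seed = seed),
                       data = dtrain, nrounds = params$nrounds, verbose = 0)
  } else {
    dtrain <- xgboost::xgb.DMatrix(X[keep, , drop = FALSE], label = y[keep],
                                   missing = NA)
    xgboost::xgb.train(params = list(objective = "reg:absoluteerror",
                                     max_depth = params$max_depth,
                                     subsample = params$subsample,
                                     eta = params$eta, nthread = 1,
                                     seed = seed),
                       data = dtrain, nrounds = params$nrounds, verbose = 0)
  }
}

sample_targets <- function(samples) {
  list(diagnosis = dx_severity(samples$target_diagnosis),
       mmse = samples$target_mmse,
       ventricle = samples$target_ventricle_icv)
}

# gap to the most recent observation of each target variable (the same
# quantity as the time_since_mr_* features)
sample_gaps <- function(features) {
  list(diagnosis = features$time_since_mr_dx,
       mmse = features$time_since_mr_mmse,
       ventricle = features$time_since_mr_ventricle_icv)
}

#' Train the gradient-boosted forecasters
#'
#' With `windows = NULL`, one model per target variable (3 estimators, the
#' no-window variant). With an [l2c_windows()] spec, one model per (target,
#' window) cell trained only on samples whose forecast gap falls in the
#' window (15 estimators, the windowed variant). Missing feature values are
#' passed through to the tree learner; no imputation or normalisation.
#'
#' @param samples Training samples from [l2c_training_samples()].
#' @param params [xgb_params()].
#' @param windows `NULL` or an [l2c_windows()] spec.
#' @param seed Integer seed.
#' @return An `l2c_bundle` of variant `"xgb_nw"` or `"xgb_w"`.
#' @export
train_xgb <- function(samples, params = xgb_params(), windows = NULL,
                      seed = 1) {
  X <- xgb_feature_matrix(samples)
  ys <- sample_targets(samples)
  if (is.null(windows)) {
    est <- lapply(TARGETS, function(tg)
      fit_one_xgb(X, ys[[tg]], tg, params, seed))
    names(est) <- TARGETS
    if (any(vapply(est, is.null, logical(1)))) {
      stop("a target variable has no observed training samples")
    }
    return(new_bundle("xgb_nw", est, config = params, seed = seed))
  }
  gaps <- sample_gaps(samples)
  est <- list()
  for (tg in TARGETS) {
    widx <- select_window(gaps[[tg]], tg, windows)
    tab <- windows[[tg]]
    est[[tg]] <- lapply(seq_len(nrow(tab)), function(w) {
      in_w <- !is.na(widx) & widx == w & !is.na(ys[[tg]])
      if (!any(in_w)) {
        stop(sprintf("no training samples for target '%s' in window %s",
                     tg, tab$label[w]))
      }
      fit_one_xgb(X[in_w, , drop = FALSE], ys[[tg]][in_w], tg, params,
                  seed + w)
    })
  }
  new_bundle("xgb_w", est, windows = windows, config = params, seed = seed)
}

# ---- bundle ------------------------------------------------------------

bundle_estimator_count <- function(bundle) {
  switch(bundle$variant,
         fnn = 1L,
         xgb_nw = length(bundle$estimators),
         xgb_w = sum(lengths(bundle$estimators)),
         carry_forward = 0L)
}

#' Construct a model bundle
#'
#' A bundle pairs a trained forecaster with its frozen preprocessing state
#' (network variant), window spec (windowed-tree variant) and seed/config.
#' Estimator cardinality is validated on construction: 1 (fnn), 3 (xgb_nw),
#' 15 (xgb_w).
#'
#' @param variant One of `"fnn"`, `"xgb_nw"`, `"xgb_w"`, `"carry_forward"`.
#' @param estimators Trained estimator(s).
#' @param preprocess `l2c_preprocess` state (fnn only).
#' @param windows [l2c_windows()] spec (xgb_w only).
#' @param config Training configuration.
#' @param seed Training seed.
#' @param extra Named list of variant-specific state.
#' @return An `l2c_bundle`.
#' @export
new_bundle <- function(variant, estimators, preprocess = NULL, windows = NULL,
                       config = NULL, seed = NULL, extra = list()) {
  variant <- match.arg(variant, c("fnn", "xgb_nw", "xgb_w", "carry_forward"))
  bundle <- structure(list(variant = variant, estimators = estimators,
                           preprocess = preprocess, windows = windows,
                           config = config, seed = seed, extra = extra),
                      class = "l2c_bundle")
  n_est <- bundle_estimator_count(bundle)
  expected <- c(fnn = 1L, xgb_nw = 3L, xgb_w = 15L, carry_forward = 0L)[variant]
  if (variant == "xgb_w") {
    expected <- sum(vapply(windows, nrow, integer(1)))
  }
  if (n_est != expected) {
    stop(sprintf("%s bundle must hold %d estimator(s), got %d",
                 variant, expected, n_est))
  }
  bundle
}

#' Train the multi-task network on L2C training samples
#'
#' Fits the preprocessing state (median imputation, Gauss-rank, one-hot with
#' unknown class, `time_since_milder` dropped) on these samples, transforms
#' the features and regression targets, and trains the network with the
#' masked equal-weighted multi-task loss.
#'
#' @param samples Training samples from [l2c_training_samples()].
#' @param config [fnn_config()].
#' @return An `l2c_bundle` of variant `"fnn"`.
#' @export
train_fnn_bundle <- function(samples, config = fnn_config()) {
  state <- fit_preprocess(samples[, l2c_feature_names()],
                          targets = list(mmse = samples$target_mmse,
                                         ventricle_icv = samples$target_ventricle_icv))
  X <- apply_preprocess(state, samples)
  dx_idx <- dx_severity(samples$target_diagnosis) + 1L
  y_mmse <- apply_gauss_rank(state$target_maps$mmse, samples$target_mmse)
  y_vent <- apply_gauss_rank(state$target_maps$ventricle_icv,
                             samples$target_ventricle_icv)
  fit <- train_fnn(X, dx_idx, y_mmse, y_vent, config)
  new_bundle("fnn", list(fit), preprocess = state, config = config,
             seed = config$seed)
}

#' Train the carry-forward (last observation carried forward) baseline
#'
#' Stores the training cohort's median MMSE and ICV-normalised ventricle
#' volume as fallbacks for never-observed histories.
#'
#' @param samples Training samples (used only for the fallback medians).
#' @return An `l2c_bundle` of variant `"carry_forward"`.
#' @export
train_carry_forward <- function(samples) {
  new_bundle("carry_forward", list(),
             extra = list(mmse_median = stats::median(samples$target_mmse,
                                                      na.rm = TRUE),
                          ventricle_median = stats::median(samples$target_ventricle_icv,
                                                           na.rm = TRUE)))
}
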