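# Batch prediction from a model bundle and the open-horizon monthly grid.

clip_predictions <- function(pred) {
  pred$mmse <- pmin(pmax(pred$mmse, 0), 30)
  pred$ventricle_icv <- pmax(pred$ventricle_icv, 0)
  pred
}

#' Predict the three targets for a table of L2C feature rows
#'
#' Dispatches on the bundle variant. Network predictions pass through the
#' frozen preprocessing state and are inverse-Gauss-rank transformed to raw
#' units; MMSE is clipped to `[0, 30]` and ventricle/ICV to non-negative.
#' The windowed tree variant routes each row to the window containing its
#' forecast gap; rows whose target variable was never observed get `NA`
#' (prediction unavailable). The carry-forward baseline repeats the most
#' recent observed value (probability 1 on the last diagnosis; uniform and
#' training medians when never observed).
#'
#' @param bundle An `l2c_bundle`.
#' @param features Tibble with the 70 L2C columns (e.g. from
#'   [l2c_transform()]).
#' @return Tibble with columns `p_cn`, `p_mci`, `p_dem`, `mmse`,
#'   `ventricle_icv`; diagnosis probabilities sum to 1 where available.
#' @export
predict_bundle <- function(bundle, features) {
  stopifnot(inherits(bundle, "l2c_bundle"))
  n <- nrow(features)
  out <- tibble::tibble(p_cn = rep(NA_real_, n), p_mci = NA_real_,
                        p_dem = NA_real_, mmse = NA_real_,
                        ventricle_icv = NA_real_)
  if (n == 0) return(out)

  if (bundle$variant == "fnn") {
    X <- apply_preprocess(bundle$preprocess, features)
    raw <- predict_fnn_raw(bundle$estimators[[1]], X)
    out$p_cn <- raw[, "p_cn"]; out$p_mci <- raw[, "p_mci"]
    out$p_dem <- raw[, "p_dem"]
    out$mmse <- inverse_gauss_rank(bundle$preprocess$target_maps$mmse,
                                   raw[, "mmse_gr"])
    out$ventricle_icv <- inverse_gauss_rank(
      bundle$preprocess$target_maps$ventricle_icv, raw[, "vent_gr"])
    return(clip_predictions(out))
  }

  if (bundle$variant == "carry_forward") {
    sev <- dx_severity(features$mr_dx)
    probs <- matrix(1 / 3, n, 3)
    obs <- !is.na(sev)
    probs[obs, ] <- 0
    probs[cbind(which(obs), sev[obs] + 1L)] <- 1
    out$p_cn <- probs[, 1]; out$p_mci <- probs[, 2]; out$p_dem <- probs[, 3]
    out$mmse <- ifelse(is.na(features$mr_mmse), bundle$extra$mmse_median,
                       features$mr_mmse)
    out$ventricle_icv <- ifelse(is.na(features$mr_ventricle_icv),
                                bundle$extra$ventricle_median,
                                features$mr_ventricle_icv)
    return(clip_predictions(out))
  }

  X <- xgb_feature_matrix(features)
  if (bundle$variant == "xgb_nw") {
    probs <- softprob_matrix(predict(bundle$estimators$diagnosis, X))
    out$p_cn <- probs[, 1]; out$p_mci <- probs[, 2]; out$p_dem <- probs[, 3]
    out$mmse <- predict(bundle$estimators$mmse, X)
    out$ventricle_icv <- predict(bundle$estimators$ventricle, X)
    return(clip_predictions(out))
  }

  # xgb_w: route rows per target through the window containing their gap
  gaps <- sample_gaps(features)
  for (tg in TARGETS) {
    widx <- select_window(gaps[[tg]], tg, bundle$windows)
    for (w in unique(widx[!is.na(widx)])) {
      rows <- which(!is.na(widx) & widx == w)
      est <- bundle$estimators[[tg]][[w]]
      if (tg == "diagnosis") {
        probs <- softprob_matrix(predict(est, X[rows, , drop = FALSE]))
        out$p_cn[rows] <- probs[, 1]; out$p_mci[rows] <- probs[, 2]
        out$p_dem[rows] <- probs[, 3]
      } else if (tg == "mmse") {
        out$mmse[rows] <- predict(est, X[rows, , drop = FALSE])
      } else {
        out$ventricle_icv[rows] <- predict(est, X[rows, , drop = FALSE])
      }
    }
  }
  clip_predictions(out)
}

#' Open-horizon monthly forecast grid
#'
#' For each participant, assembles L2C features at every month
#' `1..horizon_months` past the last observed visit and predicts all three
#' targets, producing TADPOLE-style monthly rows.
#'
#' @param bundle An `l2c_bundle`.
#' @param cohort Cohort tibble of input (observed) visits, ICV-normalised.
#' @param horizon_months Forecast horizon (default 120): a scalar, or a
#'   named vector giving a per-participant horizon.
#' @return An `l2c_forecast` tibble: `participant_id`, `month` (months since
#'   participant baseline), `horizon` (months past last visit), `p_cn`,
#'   `p_mci`, `p_dem`, `mmse`, `ventricle_icv`.
#' @export
forecast_monthly <- function(bundle, cohort, horizon_months = 120) {
  stopifnot(all(horizon_months >= 1))
  parts <- split(seq_len(nrow(cohort)), cohort$participant_id)
  feats <- lapply(parts, function(idx) {
    visits <- cohort[idx, , drop = FALSE]
    id <- visits$participant_id[1]
    h <- if (length(horizon_months) == 1) horizon_months else
      horizon_months[[id]]
    last <- max(visits$month)
    tfs <- last + seq_len(h)
    dplyr::bind_cols(
      tibble::tibble(participant_id = id,
                     month = tfs, horizon = seq_len(h)),
      l2c_grid(prefix_summary(visits), tfs))
  })
  feats <- dplyr::bind_rows(feats)
  pred <- predict_bundle(bundle, feats)
  out <- dplyr::bind_cols(feats[, c("participant_id", "month", "horizon")], pred)
  class(out) <- c("l2c_forecast", class(out))
  out
}
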