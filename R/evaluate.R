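# Metrics (pooled multiclass AUC, per-participant MAE/RMSE), statistical
# tests (corrected resampled t, permutation, paired t, BH-FDR) and the
# stratification helpers (horizon bins, diagnostic subgroups, modality
# ablation).

#' Match forecast-grid rows to target visits
#'
#' Each target visit pairs with the grid row of the same participant whose
#' month is nearest to the visit month (ties resolve to the earlier grid
#' month). Visits beyond the grid horizon are excluded and counted.
#'
#' @param grid An `l2c_forecast` tibble from [forecast_monthly()].
#' @param target_visits Cohort tibble of target (second-half) visits.
#' @return Tibble of pairs: participant, visit month, matched grid row's
#'   predictions, the truths (`true_diagnosis`, `true_mmse`,
#'   `true_ventricle_icv`) and `horizon` (months past last input visit);
#'   `attr(, "n_beyond_horizon")` counts dropped visits.
#' @export
match_forecasts <- function(grid, target_visits) {
  if (nrow(grid) == 0) stop("empty forecast grid")
  dropped <- 0L
  parts <- split(seq_len(nrow(target_visits)), target_visits$participant_id)
  res <- lapply(names(parts), function(id) {
    tv <- target_visits[parts[[id]], , drop = FALSE]
    g <- grid[grid$participant_id == id, , drop = FALSE]
    if (nrow(g) == 0) {
      dropped <<- dropped + nrow(tv)
      return(NULL)
    }
    beyond <- tv$month > max(g$month)
    dropped <<- dropped + sum(beyond)
    tv <- tv[!beyond, , drop = FALSE]
    if (nrow(tv) == 0) return(NULL)
    gi <- vapply(tv$month, function(mo) {
      d <- abs(g$month - mo)
      which(d == min(d))[1]  # ties -> earlier grid month (rows month-ordered)
    }, integer(1))
    tibble::tibble(
      participant_id = id, visit_month = tv$month,
      grid_month = g$month[gi], horizon = g$horizon[gi],
      p_cn = g$p_cn[gi], p_mci = g$p_mci[gi], p_dem = g$p_dem[gi],
      mmse = g$mmse[gi], ventricle_icv = g$ventricle_icv[gi],
      true_diagnosis = tv$diagnosis, true_mmse = as.numeric(tv$mmse),
      true_ventricle_icv = tv$ventricle_icv)
  })
  out <- dplyr::bind_rows(res)
  attr(out, "n_beyond_horizon") <- dropped
  out
}

auc_rank <- function(scores, positive) {
  r <- rank(scores)  # average ranks give the tie-corrected AUC
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Pooled multiclass AUC
#'
#' Mean of the three one-vs-rest two-class AUCs (CN vs not-CN, MCI vs
#' not-MCI, DEM vs not-DEM) computed by the tie-corrected rank statistic on
#' predictions pooled over all participants and time points. Pairs with a
#' missing true diagnosis are excluded; a class absent from the pooled truth
#' (or with no negatives) is skipped with a message and the mean is taken
#' over the computable classes.
#'
#' @param probs Matrix/data frame with columns ordered (CN, MCI, DEM), or a
#'   pairs tibble from [match_forecasts()].
#' @param truth Character truths in `c("CN", "MCI", "DEM")` (ignored when
#'   `probs` is a pairs tibble).
#' @return The mAUC in `[0, 1]`.
#' @export
mauc <- function(probs, truth = NULL) {
  if (is.data.frame(probs) && all(c("p_cn", "true_diagnosis") %in% names(probs))) {
    truth <- probs$true_diagnosis
    probs <- as.matrix(probs[, c("p_cn", "p_mci", "p_dem")])
  }
  probs <- as.matrix(probs)
  keep <- !is.na(truth) & stats::complete.cases(probs)
  probs <- probs[keep, , drop = FALSE]; truth <- truth[keep]
  sev <- dx_severity(truth)
  aucs <- vapply(seq_along(DX_LEVELS), function(k) {
    pos <- sev == (k - 1)
    if (!any(pos) || all(pos)) return(NA_real_)
    auc_rank(probs[, k], pos)
  }, numeric(1))
  if (all(is.na(aucs))) stop("no class with both positives and negatives")
  if (anyNA(aucs)) {
    message("skipping class(es) absent from pooled truth: ",
            paste(DX_LEVELS[is.na(aucs)], collapse = ", "))
  }
  mean(aucs, na.rm = TRUE)
}

#' Per-participant mean absolute error (and RMSE)
#'
#' Absolute errors are averaged across all forecast time points within each
#' participant first; the report then averages those per-participant values.
#' Participants with no observed truth for the variable are excluded and
#' counted.
#'
#' @param pairs Pairs tibble from [match_forecasts()].
#' @param variable `"mmse"` or `"ventricle_icv"`.
#' @return List: `per_participant` tibble (id, mae, rmse, n), `mae`, `rmse`
#'   (means across participants), `mae_sd`, `n_participants`, `n_excluded`.
#' @export
mae_by_participant <- function(pairs, variable = c("mmse", "ventricle_icv")) {
  variable <- match.arg(variable)
  truth_col <- paste0("true_", variable)
  err <- pairs[[variable]] - pairs[[truth_col]]
  ok <- !is.na(err)
  df <- tibble::tibble(participant_id = pairs$participant_id, err = err)[ok, ]
  per <- dplyr::summarise(dplyr::group_by(df, .data$participant_id),
                          mae = mean(abs(.data$err)),
                          rmse = sqrt(mean(.data$err^2)),
                          n = dplyr::n(), .groups = "drop")
  n_excluded <- length(unique(pairs$participant_id)) - nrow(per)
  list(per_participant = per,
       mae = mean(per$mae), mae_sd = stats::sd(per$mae),
       rmse = mean(per$rmse),
       n_participants = nrow(per), n_excluded = n_excluded)
}

#' Corrected resampled t-test for cross-validated performance differences
#'
#' Because training sets overlap across folds, fold-level metric differences
#' are positively correlated; the test statistic inflates the variance by
#' `(1/k + rho)` with `rho` the test/train size ratio (default 1/19 for a
#' 20-partition design with one test partition against 19 partitions that
#' influence the model):
#' `t = mean(d) / sqrt((1/k + rho) * var(d))`, compared with a Student t on
#' `k - 1` degrees of freedom. `rho = 0` recovers the classical one-sample
#' t-test.
#'
#' @param per_fold_diffs Numeric vector of fold-level metric differences.
#' @param rho Train/test overlap correction (default `1/19`).
#' @return An `l2c_test` with `statistic`, `p_value`, `method`, `k`, `rho`.
#' @export
corrected_resampled_ttest <- function(per_fold_diffs, rho = 1 / 19) {
  k <- length(per_fold_diffs)
  if (k < 2) stop("need at least two folds")
  if (rho < 0) stop("rho must be non-negative")
  m <- mean(per_fold_diffs)
  v <- stats::var(per_fold_diffs)
  if (v == 0) {
    if (m == 0) {
      t_stat <- 0; p <- 1
    } else {
      warning("zero variance with nonzero mean difference")
      t_stat <- sign(m) * Inf; p <- 0
    }
  } else {
    t_stat <- m / sqrt((1 / k + rho) * v)
    p <- 2 * stats::pt(-abs(t_stat), df = k - 1)
  }
  structure(list(statistic = t_stat, p_value = p,
                 method = "corrected_resampled_t", k = k, rho = rho),
            class = "l2c_test")
}

#' Permutation test for a pooled mAUC difference between two models
#'
#' The statistic is `|mAUC_A - mAUC_B|` on the identical pooled
#' (participant, time point) set. The null distribution swaps the two
#' models' probability rows independently per time point with probability
#' 1/2; the p-value uses add-one smoothing,
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param probs_a,probs_b Matrices of (CN, MCI, DEM) probabilities, same
#'   rows.
#' @param truth Character truths.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return An `l2c_test` with `statistic`, `p_value`, `n_perm`.
#' @export
permutation_test_mauc <- function(probs_a, probs_b, truth, n_perm = 1000,
                                  seed = 1) {
  probs_a <- as.matrix(probs_a); probs_b <- as.matrix(probs_b)
  if (!identical(dim(probs_a), dim(probs_b)) ||
      nrow(probs_a) != length(truth)) {
    stop("the two models' prediction sets do not match")
  }
  observed <- abs(mauc(probs_a, truth) - mauc(probs_b, truth))
  set.seed(seed)
  n <- nrow(probs_a)
  null_ge <- 0L
  for (b in seq_len(n_perm)) {
    swap <- stats::runif(n) < 0.5
    pa <- probs_a; pb <- probs_b
    pa[swap, ] <- probs_b[swap, ]; pb[swap, ] <- probs_a[swap, ]
    stat <- abs(mauc(pa, truth) - mauc(pb, truth))
    if (stat >= observed) null_ge <- null_ge + 1L
  }
  structure(list(statistic = observed,
                 p_value = (1 + null_ge) / (1 + n_perm),
                 method = "permutation", n_perm = n_perm),
            class = "l2c_test")
}

#' Paired t-test on per-participant errors
#'
#' @param errors_a,errors_b Per-participant metric values for two models on
#'   the same participants.
#' @return An `l2c_test`.
#' @export
paired_ttest <- function(errors_a, errors_b) {
  tt <- stats::t.test(errors_a, errors_b, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                 method = "paired_t", k = length(errors_a)),
            class = "l2c_test")
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' @param p_values Numeric p-values.
#' @param q FDR level (default 0.05).
#' @return Logical rejection flags (step-up procedure at level `q`).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Horizon year bin of a forecast
#'
#' The gap between the last input visit and the target month maps to yearly
#' bins: `(0, 12] -> 1`, `(12, 24] -> 2`, ..., capped at bin 6 (a 10-month
#' gap is "1 year into the future"; a gap exactly on a 12-month boundary
#' belongs to the lower bin).
#'
#' @param last_input_month,target_month Numeric months.
#' @return Integer bin(s) 1..6.
#' @export
bin_by_horizon <- function(last_input_month, target_month) {
  gap <- target_month - last_input_month
  if (any(gap <= 0)) stop("target month must lie after the last input visit")
  pmin(ceiling(gap / 12), 6)
}

#' Diagnostic subgroup from the last observed input diagnosis
#'
#' @param input_visits Cohort tibble of input-half visits.
#' @return Tibble `participant_id`, `subgroup` (CN/MCI/DEM); participants
#'   with no observed input diagnosis are excluded and counted in
#'   `attr(, "n_excluded")`.
#' @export
subgroup_by_last_dx <- function(input_visits) {
  per <- dplyr::summarise(
    dplyr::group_by(input_visits, .data$participant_id),
    subgroup = {
      obs <- !is.na(.data$diagnosis)
      if (any(obs)) .data$diagnosis[max(which(obs))] else NA_character_
    },
    .groups = "drop")
  out <- per[!is.na(per$subgroup), , drop = FALSE]
  attr(out, "n_excluded") <- sum(is.na(per$subgroup))
  out
}

#' Set one modality block to missing across input visits
#'
#' Blanks every column of the chosen modality (`mri`: the six volumes and
#' their normalised versions; `cognitive`: MMSE and CDR; `diagnosis`) on the
#' input half of each participant's visits, leaving target visits untouched.
#'
#' @param cohort Cohort tibble.
#' @param modality One of `"mri"`, `"cognitive"`, `"diagnosis"`, or `"none"`
#'   (identity).
#' @param input_only If `TRUE` (default) only the first-half visits are
#'   ablated; if `FALSE`, all rows passed in.
#' @return The ablated cohort.
#' @export
ablate_modality <- function(cohort, modality, input_only = TRUE) {
  if (identical(modality, "none")) return(cohort)
  modality <- match.arg(modality, names(MODALITY_COLS))
  cols <- intersect(MODALITY_COLS[[modality]], names(cohort))
  rows <- if (input_only) {
    unlist(lapply(split(seq_len(nrow(cohort)), cohort$participant_id),
                  function(idx) {
                    mo <- cohort$month[idx]
                    idx[order(mo)][seq_len(ceiling(length(idx) / 2))]
                  }), use.names = FALSE)
  } else {
    seq_len(nrow(cohort))
  }
  for (col in cols) cohort[[col]][rows] <- NA
  cohort
}

#' Per-modality performance deltas from ablation reports
#'
#' Differences between each ablated scenario's metrics and the full-feature
#' scenario, signed so that positive means degradation (mAUC drop, error
#' increase).
#'
#' @param reports Metric tibble with a `scenario` column (one value
#'   `"full"`, others the ablated modalities) and metric columns `mauc`,
#'   `mmse_mae`, `ventricle_mae`.
#' @return Tidy tibble: one row per (modality, metric) with `delta`.
#' @export
feature_importance_by_ablation <- function(reports) {
  stopifnot("full" %in% reports$scenario)
  full <- reports[reports$scenario == "full", , drop = FALSE]
  abl <- reports[reports$scenario != "full", , drop = FALSE]
  metrics <- c(mauc = -1, mmse_mae = 1, ventricle_mae = 1)  # sign -> degradation
  rows <- lapply(seq_len(nrow(abl)), function(i) {
    tibble::tibble(modality = abl$scenario[i],
                   metric = names(metrics),
                   delta = unname(vapply(names(metrics), function(mname)
                     metrics[[mname]] * (abl[[mname]][i] - full[[mname]][1]),
                     numeric(1))))
  })
  dplyr::bind_rows(rows)
}
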