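# Fold-level experiment harness: participant-level cross-validation,
# first-half/second-half evaluation, and the stratified further analyses
# (horizon years, diagnostic subgroups, modality ablation, input-visit
# truncation).

ANALYSES <- c("main", "horizon", "n_input_timepoints", "subgroup",
              "ablation", "importance")

pairs_metrics <- function(pairs) {
  m <- tryCatch(suppressMessages(mauc(pairs)), error = function(e) NA_real_)
  mm <- mae_by_participant(pairs, "mmse")
  vv <- mae_by_participant(pairs, "ventricle_icv")
  tibble::tibble(mauc = m,
                 mmse_mae = mm$mae, mmse_rmse = mm$rmse,
                 ventricle_mae = vv$mae, ventricle_rmse = vv$rmse,
                 n_participants = length(unique(pairs$participant_id)),
                 n_timepoints = nrow(pairs))
}

fit_variant <- function(variant, samples, fnn_cfg, xgb_par, seed) {
  switch(variant,
         fnn = {
           cfg <- fnn_cfg %||% fnn_config(seed = seed)
           cfg$seed <- seed
           train_fnn_bundle(samples, cfg)
         },
         xgb_nw = train_xgb(samples, xgb_par %||% xgb_params(), windows = NULL,
                            seed = seed),
         xgb_w = train_xgb(samples, xgb_par %||% xgb_params(),
                           windows = l2c_windows(), seed = seed),
         carry_forward = train_carry_forward(samples),
         stop("unknown variant: ", variant))
}

# split a test cohort into input/target halves; returns list of tibbles
split_cohort_half <- function(cohort) {
  parts <- split(seq_len(nrow(cohort)), cohort$participant_id)
  parts <- parts[vapply(parts, length, integer(1)) >= 2]
  inputs <- vector("list", length(parts)); targets <- inputs
  for (j in seq_along(parts)) {
    visits <- cohort[parts[[j]], , drop = FALSE]
    visits <- visits[order(visits$month), , drop = FALSE]
    halves <- split_half(visits)
    inputs[[j]] <- halves$input; targets[[j]] <- halves$target
  }
  list(input = dplyr::bind_rows(inputs), target = dplyr::bind_rows(targets))
}

# forecast a test cohort's second-half visits through the monthly grid
evaluate_halves <- function(bundle, input, target, horizon_cap = 120) {
  last_in <- tapply(input$month, input$participant_id, max)
  max_tgt <- tapply(target$month, target$participant_id, max)
  ids <- names(last_in)
  horizons <- pmax(1, pmin(horizon_cap,
                           ceiling(max_tgt[ids] - last_in[ids])))
  names(horizons) <- ids
  grid <- forecast_monthly(bundle, input, horizons)
  pairs <- match_forecasts(grid, target)
  pairs$last_input_month <- as.numeric(last_in[pairs$participant_id])
  pairs
}

#' Run the cross-validated forecasting experiment
#'
#' Partitions participants into `k` folds (test fold rotating, validation
#' the next fold, remainder training), trains each requested variant on the
#' training participants' full histories, forecasts the test participants'
#' second-half visits through the monthly grid, and computes pooled mAUC
#' and per-participant MAE/RMSE, optionally stratified by horizon year,
#' diagnostic subgroup, modality ablation (restricted to participants with
#' every feature observed at least once in their input half) and number of
#' input time points (participants with at least four input visits,
#' truncated to their first 1-4 visits with unchanged target visits).
#'
#' @param cohort Eligible, ICV-normalised cohort tibble.
#' @param variants Character subset of
#'   `c("fnn", "xgb_nw", "xgb_w", "carry_forward")`.
#' @param k Number of folds (default 20).
#' @param seed Integer seed (fold shuffle and per-fold training seeds derive
#'   from it).
#' @param folds_to_run Integer fold indices to execute (default all).
#' @param analyses Subset of `c("main", "horizon", "n_input_timepoints",
#'   "subgroup", "ablation", "importance")`.
#' @param horizon_cap Maximum forecast horizon in months (default 120).
#' @param fnn_cfg,xgb_par Optional configs overriding the defaults.
#' @param n_trials Random-search trials for hyperparameter tuning on the
#'   validation fold (0 = use the supplied/default configuration).
#' @return An `l2c_experiment`: `metrics` (one tidy row per variant x fold x
#'   analysis x stratum), `pairs` (main-analysis pooled pairs per variant and
#'   fold) and the fold definition.
#' @export
run_experiment <- function(cohort,
                           variants = c("carry_forward", "xgb_nw"),
                           k = 20, seed = 1, folds_to_run = NULL,
                           analyses = "main", horizon_cap = 120,
                           fnn_cfg = NULL, xgb_par = NULL, n_trials = 0) {
  analyses <- match.arg(analyses, ANALYSES, several.ok = TRUE)
  ids <- unique(cohort$participant_id)
  folds <- kfold_partition(ids, k = k, seed = seed)
  folds_to_run <- folds_to_run %||% seq_len(k)
  metric_rows <- list()
  pair_store <- list()

  for (fi in folds_to_run) {
    fold <- folds[[fi]]
    if (length(fold$test_ids) == 0) stop("fold with empty test set")
    train <- cohort[cohort$participant_id %in% fold$train_ids, , drop = FALSE]
    val <- cohort[cohort$participant_id %in% fold$val_ids, , drop = FALSE]
    test <- cohort[cohort$participant_id %in% fold$test_ids, , drop = FALSE]
    samples <- l2c_training_samples(train)
    halves <- split_cohort_half(test)

    for (variant in variants) {
      fit_seed <- seed * 1000L + fi
      cfg_fnn <- fnn_cfg; par_xgb <- xgb_par
      if (n_trials > 0 && variant != "carry_forward") {
        tuned <- tune_variant(variant, samples, val, n_trials = n_trials,
                              seed = fit_seed, horizon_cap = horizon_cap)
        if (variant == "fnn") cfg_fnn <- tuned else par_xgb <- tuned
      }
      bundle <- fit_variant(variant, samples, cfg_fnn, par_xgb, fit_seed)
      pairs <- evaluate_halves(bundle, halves$input, halves$target, horizon_cap)
      pair_store[[variant]][[as.character(fi)]] <- pairs

      add_row <- function(p, analysis, stratum) {
        metric_rows[[length(metric_rows) + 1]] <<- dplyr::bind_cols(
          tibble::tibble(variant = variant, fold = fi, analysis = analysis,
                         stratum = stratum),
          pairs_metrics(p))
      }
      add_row(pairs, "main", "all")

      if ("horizon" %in% analyses) {
        bins <- bin_by_horizon(pairs$last_input_month, pairs$visit_month)
        for (b in sort(unique(bins))) {
          add_row(pairs[bins == b, , drop = FALSE], "horizon",
                  sprintf("year_%d", b))
        }
      }
      if ("subgroup" %in% analyses) {
        sg <- subgroup_by_last_dx(halves$input)
        for (g in DX_LEVELS) {
          in_g <- pairs$participant_id %in%
            sg$participant_id[sg$subgroup == g]
          if (any(in_g)) add_row(pairs[in_g, , drop = FALSE], "subgroup", g)
        }
      }
      if (any(c("ablation", "importance") %in% analyses)) {
        full_ids <- full_feature_ids(halves$input)
        keep <- test$participant_id %in% full_ids
        if (any(keep)) {
          sub <- test[keep, , drop = FALSE]
          for (scen in c("none", "mri", "cognitive", "diagnosis")) {
            abl <- ablate_modality(sub, scen, input_only = TRUE)
            h2 <- split_cohort_half(abl)
            p2 <- evaluate_halves(bundle, h2$input, h2$target, horizon_cap)
            add_row(p2, "ablation", if (scen == "none") "full" else scen)
          }
        }
      }
      if ("n_input_timepoints" %in% analyses) {
        cond_ids <- names(which(table(halves$input$participant_id) >= 4))
        if (length(cond_ids) > 0) {
          inp <- halves$input[halves$input$participant_id %in% cond_ids, ]
          tgt <- halves$target[halves$target$participant_id %in% cond_ids, ]
          for (j in 1:4) {
            inp_j <- dplyr::slice_head(
              dplyr::group_by(dplyr::arrange(inp, .data$participant_id,
                                             .data$month),
                              .data$participant_id), n = j)
            inp_j <- dplyr::ungroup(inp_j)
            pj <- evaluate_halves(bundle, inp_j, tgt, horizon_cap)
            add_row(pj, "n_input_timepoints", sprintf("n_input_%d", j))
          }
        }
      }
    }
  }
  metrics <- dplyr::bind_rows(metric_rows)
  structure(list(metrics = metrics, pairs = pair_store, folds = folds,
                 k = k, seed = seed, analyses = analyses),
            class = "l2c_experiment")
}

# participants with at least one observed value for every recurring feature
# across their input visits (the "full feature set" restriction)
full_feature_ids <- function(input_visits) {
  cols <- c("mmse", "cdr_global", ROI_COLS, "icv", "diagnosis")
  per <- lapply(split(seq_len(nrow(input_visits)),
                      input_visits$participant_id),
                function(idx) {
                  all(vapply(cols, function(col)
                    any(!is.na(input_visits[[col]][idx])), logical(1)))
                })
  names(per)[unlist(per)]
}

#' Compare two variants across folds with the corrected resampled t-test
#'
#' @param experiment An `l2c_experiment`.
#' @param variant_a,variant_b Variant tags present in the experiment.
#' @param metric Metric column (default `"mauc"`).
#' @param rho Overlap correction (default `1/19`).
#' @return An `l2c_test` on the fold-level differences (a - b).
#' @export
compare_folds <- function(experiment, variant_a, variant_b, metric = "mauc",
                          rho = 1 / 19) {
  m <- experiment$metrics
  m <- m[m$analysis == "main", , drop = FALSE]
  a <- m[m$variant == variant_a, , drop = FALSE]
  b <- m[m$variant == variant_b, , drop = FALSE]
  a <- a[order(a$fold), ]; b <- b[order(b$fold), ]
  stopifnot(identical(a$fold, b$fold))
  corrected_resampled_ttest(a[[metric]] - b[[metric]], rho = rho)
}

# ---- validation-fold random search -------------------------------------

sample_xgb_params <- function() {
  xgb_params(max_depth = sample(3:8, 1),
             subsample = stats::runif(1, 0.4, 1),
             eta = exp(stats::runif(1, log(0.01), log(0.2))))
}

sample_fnn_config <- function(seed) {
  fnn_config(n_hidden_layers = sample(2:5, 1),
             hidden_size = sample(128:512, 1),
             dropout = stats::runif(1, 0, 0.5),
             leaky_slope = stats::runif(1, 0.01, 0.1),
             l2_weight = 10^stats::runif(1, -7, -4),
             momentum = stats::runif(1, 0, 0.9),
             learning_rate = 10^stats::runif(1, -5, -1),
             lr_gamma = stats::runif(1, 0.1, 0.9),
             seed = seed)
}

# equal-weighted validation score: mAUC minus MAEs normalised by the
# validation truth SD (higher is better)
validation_score <- function(pairs) {
  m <- tryCatch(suppressMessages(mauc(pairs)), error = function(e) 0)
  norm_mae <- function(variable) {
    r <- mae_by_participant(pairs, variable)
    s <- stats::sd(pairs[[paste0("true_", variable)]], na.rm = TRUE)
    if (is.na(s) || s == 0) 0 else r$mae / s
  }
  m - norm_mae("mmse") - norm_mae("ventricle_icv")
}

tune_variant <- function(variant, samples, val_cohort, n_trials, seed,
                         horizon_cap = 120) {
  set.seed(seed)
  halves <- split_cohort_half(val_cohort)
  best <- NULL; best_score <- -Inf
  for (trial in seq_len(n_trials)) {
    cand <- if (variant == "fnn") sample_fnn_config(seed + trial) else
      sample_xgb_params()
    bundle <- fit_variant(variant, samples,
                          if (variant == "fnn") cand else NULL,
                          if (variant != "fnn") cand else NULL,
                          seed + trial)
    pairs <- evaluate_halves(bundle, halves$input, halves$target, horizon_cap)
    sc <- validation_score(pairs)
    if (sc > best_score) {
      best <- cand; best_score <- sc
    }
  }
  best
}
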