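# The L2C (longitudinal-to-cross-sectional) transformation: collapse a
# variable-length visit history plus a forecast time tf into a fixed-length
# named feature vector, and enumerate augmented training samples.

CONT_FEATURE_STEMS <- c("mr_", "time_since_mr_", "mr_change_",
                        "low_", "time_since_low_", "high_", "time_since_high_")
DX_FEATURES <- c("mr_dx", "time_since_mr_dx", "best_dx", "time_since_best_dx",
                 "worst_dx", "time_since_worst_dx", "milder", "time_since_milder")
AUG_FEATURES <- c("age_at_tf", "sex", "education_years", "marital",
                  "apoe4_count", "months_since_baseline")
MILDER_SENTINEL <- 999

#' Names of the L2C feature vector
#'
#' Seven temporal summaries per continuous modality (8 modalities x 7 = 56),
#' eight diagnosis-history features (64 engineered in total), and six
#' augmentation covariates, giving 70 named fields.
#'
#' @param engineered_only If `TRUE`, omit the 6 augmentation covariates.
#' @return Character vector of feature names (64 or 70).
#' @export
l2c_feature_names <- function(engineered_only = FALSE) {
  cont <- unlist(lapply(CONTINUOUS_MODALITIES,
                        function(f) paste0(CONT_FEATURE_STEMS, f)))
  eng <- c(cont, DX_FEATURES)
  if (engineered_only) eng else c(eng, AUG_FEATURES)
}

#' Temporal summary features of one continuous series
#'
#' Given `(month, value)` observations strictly before the forecast time
#' `tf`, computes the seven summaries: most recent value and its time-since,
#' most recent change rate (per month, from the two most recent
#' observations), and lowest/highest historical values with their
#' times-since. Min/max ties resolve to the most recent occurrence. All
#' `time_since_*` are measured from `tf`. An empty series yields seven
#' missing values; a single observation leaves only the change rate missing.
#'
#' @param months,values Numeric vectors of observation months and values
#'   (missing values are dropped).
#' @param tf Forecast month, strictly after all observations.
#' @return Named list of the 7 features.
#' @export
continuous_features <- function(months, values, tf) {
  keep <- !is.na(values)
  months <- months[keep]; values <- values[keep]
  if (any(!is.finite(values))) stop("non-finite value in series")
  if (length(months) == 0) {
    return(list(mr = NA_real_, time_since_mr = NA_real_, mr_change = NA_real_,
                low = NA_real_, time_since_low = NA_real_,
                high = NA_real_, time_since_high = NA_real_))
  }
  if (any(months >= tf)) stop("all observations must precede tf")
  ord <- order(months)
  months <- months[ord]; values <- values[ord]
  n <- length(months)
  mr_change <- if (n >= 2) {
    (values[n] - values[n - 1]) / (months[n] - months[n - 1])
  } else NA_real_
  i_low <- max(which(values == min(values)))   # tie -> most recent
  i_high <- max(which(values == max(values)))
  list(mr = values[n], time_since_mr = tf - months[n], mr_change = mr_change,
       low = values[i_low], time_since_low = tf - months[i_low],
       high = values[i_high], time_since_high = tf - months[i_high])
}

#' Diagnosis-history features
#'
#' Summarises a `(month, diagnosis)` history (severity order CN < MCI < DEM)
#' into eight features: most recent diagnosis, best (mildest) and worst
#' historical diagnoses with the time-since of their most recent occurrence,
#' a flag for whether any historical diagnosis was strictly milder than the
#' most recent one, and the time since that milder diagnosis (sentinel 999
#' when none exists). Empty history yields all-missing.
#'
#' @param months Observation months (< `tf`).
#' @param dx Diagnosis codes in `c("CN", "MCI", "DEM")` (missing dropped).
#' @param tf Forecast month.
#' @return Named list of the 8 features.
#' @export
diagnosis_features <- function(months, dx, tf) {
  keep <- !is.na(dx)
  months <- months[keep]; dx <- dx[keep]
  sev <- dx_severity(dx)
  if (length(months) == 0) {
    return(list(mr_dx = NA_character_, time_since_mr_dx = NA_real_,
                best_dx = NA_character_, time_since_best_dx = NA_real_,
                worst_dx = NA_character_, time_since_worst_dx = NA_real_,
                milder = NA_real_, time_since_milder = NA_real_))
  }
  if (any(months >= tf)) stop("all observations must precede tf")
  ord <- order(months)
  months <- months[ord]; sev <- sev[ord]
  n <- length(months)
  i_best <- max(which(sev == min(sev)))
  i_worst <- max(which(sev == max(sev)))
  milder_idx <- which(sev < sev[n])
  milder <- as.numeric(length(milder_idx) > 0)
  t_milder <- if (milder == 1) tf - months[max(milder_idx)] else MILDER_SENTINEL
  list(mr_dx = DX_LEVELS[sev[n] + 1], time_since_mr_dx = tf - months[n],
       best_dx = DX_LEVELS[sev[i_best] + 1], time_since_best_dx = tf - months[i_best],
       worst_dx = DX_LEVELS[sev[i_worst] + 1], time_since_worst_dx = tf - months[i_worst],
       milder = milder, time_since_milder = t_milder)
}

# Collapse an input visit history into the tf-independent event summary:
# per modality, the value and month of the most recent / lowest / highest
# observation plus the recent change rate; analogous milestones for the
# diagnosis history; baseline covariates and ages for the augmentations.
prefix_summary <- function(visits) {
  visits <- visits[order(visits$month), , drop = FALSE]
  cont <- lapply(CONTINUOUS_MODALITIES, function(f) {
    v <- visits[[f]]; mo <- visits$month
    keep <- !is.na(v)
    v <- v[keep]; mo <- mo[keep]
    n <- length(v)
    if (n == 0) {
      return(list(mr_value = NA_real_, mr_month = NA_real_, mr_change = NA_real_,
                  low_value = NA_real_, low_month = NA_real_,
                  high_value = NA_real_, high_month = NA_real_))
    }
    i_low <- max(which(v == min(v)))
    i_high <- max(which(v == max(v)))
    list(mr_value = v[n], mr_month = mo[n],
         mr_change = if (n >= 2) (v[n] - v[n - 1]) / (mo[n] - mo[n - 1]) else NA_real_,
         low_value = v[i_low], low_month = mo[i_low],
         high_value = v[i_high], high_month = mo[i_high])
  })
  names(cont) <- CONTINUOUS_MODALITIES

  dxk <- !is.na(visits$diagnosis)
  dxm <- visits$month[dxk]; sev <- dx_severity(visits$diagnosis[dxk])
  dx <- if (length(dxm) == 0) {
    list(mr_dx = NA_character_, mr_month = NA_real_,
         best_dx = NA_character_, best_month = NA_real_,
         worst_dx = NA_character_, worst_month = NA_real_,
         milder = NA_real_, milder_month = NA_real_)
  } else {
    n <- length(dxm)
    i_best <- max(which(sev == min(sev)))
    i_worst <- max(which(sev == max(sev)))
    milder_idx <- which(sev < sev[n])
    list(mr_dx = DX_LEVELS[sev[n] + 1], mr_month = dxm[n],
         best_dx = DX_LEVELS[sev[i_best] + 1], best_month = dxm[i_best],
         worst_dx = DX_LEVELS[sev[i_worst] + 1], worst_month = dxm[i_worst],
         milder = as.numeric(length(milder_idx) > 0),
         milder_month = if (length(milder_idx) > 0) dxm[max(milder_idx)] else NA_real_)
  }

  age_obs <- !is.na(visits$age)
  list(cont = cont, dx = dx,
       first_month = visits$month[1],
       last_month = visits$month[nrow(visits)],
       # age advances deterministically: extrapolate from the last observed age
       age_anchor_month = if (any(age_obs)) max(visits$month[age_obs]) else NA_real_,
       age_anchor = if (any(age_obs)) visits$age[max(which(age_obs))] else NA_real_,
       sex = visits$sex[1], education_years = visits$education_years[1],
       marital = visits$marital[1], apoe4_count = visits$apoe4_count[1])
}

# Expand a prefix summary at a vector of forecast months. Returns a tibble
# with one row per tf and the 70 feature columns.
l2c_grid <- function(summary, tfs) {
  k <- length(tfs)
  out <- vector("list", 0)
  for (f in CONTINUOUS_MODALITIES) {
    s <- summary$cont[[f]]
    out[[paste0("mr_", f)]] <- rep(s$mr_value, k)
    out[[paste0("time_since_mr_", f)]] <- tfs - s$mr_month
    out[[paste0("mr_change_", f)]] <- rep(s$mr_change, k)
    out[[paste0("low_", f)]] <- rep(s$low_value, k)
    out[[paste0("time_since_low_", f)]] <- tfs - s$low_month
    out[[paste0("high_", f)]] <- rep(s$high_value, k)
    out[[paste0("time_since_high_", f)]] <- tfs - s$high_month
  }
  d <- summary$dx
  out$mr_dx <- rep(d$mr_dx, k)
  out$time_since_mr_dx <- tfs - d$mr_month
  out$best_dx <- rep(d$best_dx, k)
  out$time_since_best_dx <- tfs - d$best_month
  out$worst_dx <- rep(d$worst_dx, k)
  out$time_since_worst_dx <- tfs - d$worst_month
  out$milder <- rep(d$milder, k)
  out$time_since_milder <- if (is.na(d$milder)) {
    rep(NA_real_, k)
  } else if (d$milder == 1) {
    tfs - d$milder_month
  } else {
    rep(MILDER_SENTINEL, k)
  }
  out$age_at_tf <- summary$age_anchor + (tfs - summary$age_anchor_month) / 12
  out$sex <- rep(summary$sex, k)
  out$education_years <- rep(summary$education_years, k)
  out$marital <- rep(summary$marital, k)
  out$apoe4_count <- rep(as.numeric(summary$apoe4_count), k)
  out$months_since_baseline <- tfs - summary$first_month
  tibble::as_tibble(out)[, l2c_feature_names()]
}

#' Assemble the full L2C feature vector for one forecast time
#'
#' Concatenates the 56 continuous-modality summaries, the 8 diagnosis
#' features and 6 augmentation covariates (age at `tf` extrapolated linearly
#' from the last observed age; months since the baseline visit) into a
#' 70-field record.
#'
#' @param visits Tibble of one participant's input visits (cohort columns,
#'   ICV-normalised).
#' @param tf Forecast month, strictly after the last input visit.
#' @return One-row tibble with 70 columns (see [l2c_feature_names()]).
#' @export
assemble_features <- function(visits, tf) {
  if (nrow(visits) == 0) stop("empty visit history")
  if (any(tf <= max(visits$month))) stop("tf must lie after the visit history")
  l2c_grid(prefix_summary(visits), tf)
}

#' L2C-transform a cohort at given forecast times
#'
#' @param cohort Cohort tibble (ICV-normalised; see [normalize_by_icv()]).
#' @param forecast Tibble with columns `participant_id` and `tf`; all of a
#'   participant's visits strictly before `tf` form the input history.
#' @return Tibble: `participant_id`, `tf`, then the 70 L2C columns.
#' @export
l2c_transform <- function(cohort, forecast) {
  parts <- split(forecast, forecast$participant_id)
  res <- lapply(parts, function(fc) {
    visits <- cohort[cohort$participant_id == fc$participant_id[1], , drop = FALSE]
    rows <- lapply(fc$tf, function(tf) {
      hist <- visits[visits$month < tf, , drop = FALSE]
      if (nrow(hist) == 0) stop("no visits precede tf for participant ",
                                fc$participant_id[1])
      assemble_features(hist, tf)
    })
    dplyr::bind_cols(tibble::tibble(participant_id = fc$participant_id,
                                    tf = fc$tf),
                     dplyr::bind_rows(rows))
  })
  dplyr::bind_rows(res)
}

#' Enumerate augmented training samples from full histories
#'
#' For a participant with `m` visits, every prefix of length `p` in
#' `1..(m-1)` predicts every later visit `q` in `(p+1)..m`, yielding
#' `m * (m - 1) / 2` candidate samples; samples whose target visit has no
#' observed target variable (diagnosis, MMSE or ICV-normalised ventricle)
#' are dropped.
#'
#' @param cohort Cohort tibble (ICV-normalised).
#' @param keep_all If `TRUE`, keep samples without any observed target
#'   (useful for counting checks).
#' @return Tibble with `participant_id`, `prefix_len`, `target_visit`, `tf`,
#'   the 70 feature columns, and targets `target_diagnosis`, `target_mmse`,
#'   `target_ventricle_icv`.
#' @export
l2c_training_samples <- function(cohort, keep_all = FALSE) {
  parts <- split(seq_len(nrow(cohort)), cohort$participant_id)
  res <- vector("list", length(parts))
  for (j in seq_along(parts)) {
    visits <- cohort[parts[[j]], , drop = FALSE]
    visits <- visits[order(visits$month), , drop = FALSE]
    m <- nrow(visits)
    if (m < 2) next
    blocks <- vector("list", m - 1)
    for (p in seq_len(m - 1)) {
      qs <- (p + 1):m
      summ <- prefix_summary(visits[seq_len(p), , drop = FALSE])
      feats <- l2c_grid(summ, visits$month[qs])
      blocks[[p]] <- dplyr::bind_cols(
        tibble::tibble(participant_id = visits$participant_id[1],
                       prefix_len = p, target_visit = qs,
                       tf = visits$month[qs]),
        feats,
        tibble::tibble(target_diagnosis = visits$diagnosis[qs],
                       target_mmse = as.numeric(visits$mmse[qs]),
                       target_ventricle_icv = visits$ventricle_icv[qs]))
    }
    res[[j]] <- dplyr::bind_rows(blocks)
  }
  samples <- dplyr::bind_rows(res)
  if (!keep_all && nrow(samples) > 0) {
    has_target <- !is.na(samples$target_diagnosis) |
      !is.na(samples$target_mmse) | !is.na(samples$target_ventricle_icv)
    samples <- samples[has_target, , drop = FALSE]
  }
  samples
}
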