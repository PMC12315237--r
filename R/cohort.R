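# Cohort ingestion, cleaning, visit merging, eligibility and splitting.

#' Read a longitudinal cohort table
#'
#' Reads a CSV with one row per participant-visit using the documented column
#' dictionary (see [cohort_columns()]). Missing values are empty cells or `NA`.
#' Unknown extra columns are dropped with a warning.
#'
#' @param path Path to a CSV file.
#' @return A tibble with the documented columns.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  known <- cohort_columns()
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    raw <- raw[, intersect(names(raw), known), drop = FALSE]
  }
  missing_cols <- setdiff(known, names(raw))
  for (col in missing_cols) raw[[col]] <- NA
  out <- tibble::as_tibble(raw)[, known]
  out$participant_id <- as.character(out$participant_id)
  dplyr::arrange(out, .data$participant_id, .data$month)
}

#' Write a longitudinal cohort table
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Replace sentinel codes with missing values
#'
#' Some source tables code missingness with special integers (for example -1,
#' -4 or 999). Those codes are replaced by `NA` in the raw phenotype columns
#' only; engineered features (where 999 is a legitimate constant) are never
#' touched because cleaning happens before feature engineering.
#'
#' @param cohort Cohort tibble.
#' @param sentinels Numeric sentinel codes. Default `c(-1, -4, 999)`.
#' @param columns Phenotype columns to clean. Defaults to all numeric
#'   phenotype columns of the dictionary.
#' @return The cohort with sentinel cells set to `NA`; row count unchanged.
#' @export
clean_sentinels <- function(cohort,
                            sentinels = c(-1, -4, 999),
                            columns = c("mmse", "cdr_global", "education_years",
                                        "apoe4_count", ROI_COLS, "icv")) {
  unknown <- setdiff(columns, names(cohort))
  if (length(unknown) > 0) {
    stop("sentinel configuration references unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  for (col in columns) {
    x <- cohort[[col]]
    if (is.numeric(x)) cohort[[col]][x %in% sentinels] <- NA
  }
  cohort
}

#' Merge MRI rows into phenotype rows within a time window
#'
#' Visit tables often record cognitive/diagnostic assessments and MRI scans on
#' different dates. Each MRI row is attached to the nearest phenotype row
#' without existing MRI data within `window_months`; the merged visit keeps
#' the phenotype row's month. Equidistant candidates resolve to the earlier
#' phenotype row. MRI rows with no candidate become MRI-only visits, and no
#' MRI row is ever attached to two phenotype rows. Because only phenotype rows
#' lacking MRI data are candidates, re-merging an already-merged table is a
#' no-op.
#'
#' @param pheno_rows,mri_rows Tibbles of one participant's rows; `pheno_rows`
#'   carries cognitive/diagnosis columns, `mri_rows` carries ROI columns.
#'   Both need a `month` column.
#' @param window_months Maximum separation for a merge (default 6).
#' @return A tibble of merged visits ordered by month.
#' @export
merge_visits <- function(pheno_rows, mri_rows, window_months = 6) {
  all_cols <- cohort_columns()
  char_cols <- c("participant_id", "sex", "marital", "diagnosis")
  fill_missing <- function(df) {
    for (col in setdiff(all_cols, names(df))) {
      df[[col]] <- if (col %in% char_cols) NA_character_ else NA_real_
    }
    for (col in char_cols) df[[col]] <- as.character(df[[col]])
    df[, all_cols]
  }
  pheno <- fill_missing(tibble::as_tibble(pheno_rows))
  mri <- fill_missing(tibble::as_tibble(mri_rows))
  mri_data_cols <- c(ROI_COLS, "icv")

  has_mri <- function(df) {
    if (nrow(df) == 0) return(logical(0))
    rowSums(!is.na(df[, mri_data_cols, drop = FALSE])) > 0
  }
  pheno_open <- !has_mri(pheno)

  if (nrow(mri) > 0 && nrow(pheno) > 0) {
    ord <- order(mri$month)
    for (i in ord) {
      open_idx <- which(pheno_open)
      if (length(open_idx) == 0) break
      dist <- abs(pheno$month[open_idx] - mri$month[i])
      in_win <- dist <= window_months
      if (!any(in_win)) next
      cand <- open_idx[in_win]
      d <- dist[in_win]
      # nearest wins; equidistant -> earlier phenotype row
      best <- cand[order(d, pheno$month[cand])][1]
      for (col in mri_data_cols) pheno[[col]][best] <- mri[[col]][i]
      pheno_open[best] <- FALSE
      mri$month[i] <- NA  # consumed
    }
    mri <- mri[!is.na(mri$month), , drop = FALSE]
  }
  out <- dplyr::bind_rows(pheno, mri)
  if (nrow(out) > 0) {
    out$participant_id <- out$participant_id[which(!is.na(out$participant_id))[1]]
  }
  dplyr::arrange(out, .data$month)
}

#' Normalise ROI volumes by intracranial volume
#'
#' Adds the five ICV-normalised ROI columns (`hippocampus_icv`, ...,
#' `wholebrain_icv`), dividing each raw volume by the same visit's ICV to
#' remove head-size effects. Missingness propagates: a normalised value is
#' present iff both the raw volume and ICV are present.
#'
#' @param cohort Cohort tibble.
#' @return Cohort with the five `*_icv` columns added/overwritten.
#' @export
normalize_by_icv <- function(cohort) {
  icv <- cohort$icv
  if (any(!is.na(icv) & icv <= 0)) stop("non-positive ICV encountered")
  for (i in seq_along(ROI_COLS)) {
    cohort[[ROI_ICV_COLS[i]]] <- cohort[[ROI_COLS[i]]] / icv
  }
  cohort
}

n_recurring_visits <- function(cohort) {
  present <- rowSums(!is.na(cohort[, intersect(RECURRING_COLS, names(cohort)),
                                   drop = FALSE])) > 0
  tapply(present, cohort$participant_id, sum)
}

#' Keep participants with recurring features at two or more visits
#'
#' A visit counts if it carries at least one recurring feature (cognitive
#' score, MRI volume or clinical diagnosis); the features need not co-occur,
#' so a participant with MRI-only at visit 1 and MMSE-only at visit 2 is
#' eligible. Order of rows is preserved and the filter is idempotent.
#'
#' @param cohort Cohort tibble (visits already merged).
#' @return The eligible subset of `cohort`.
#' @export
filter_eligible <- function(cohort) {
  counts <- n_recurring_visits(cohort)
  keep <- names(counts)[counts >= 2]
  cohort[cohort$participant_id %in% keep, , drop = FALSE]
}

#' Participant-level k-fold partition with rotating validation fold
#'
#' Ids are shuffled once and split into `k` partitions. Fold `i` uses
#' partition `i` as the test set, partition `i + 1` (cyclically) as the
#' validation set, and the remaining `k - 2` partitions for training, so test
#' sets are disjoint and exhaustive and no participant serves two roles
#' within a fold.
#'
#' @param ids Character vector of unique participant ids.
#' @param k Number of folds (default 20, giving an 18:1:1 ratio).
#' @param seed Integer seed controlling the shuffle.
#' @return An object of class `l2c_folds`: a list of `k` folds, each with
#'   `fold`, `train_ids`, `val_ids`, `test_ids`.
#' @export
kfold_partition <- function(ids, k = 20, seed = 1) {
  if (anyDuplicated(ids)) stop("duplicate participant ids")
  if (k < 3) stop("k must be at least 3")
  if (length(ids) < k) stop("need at least k participants")
  set.seed(seed)
  shuffled <- sample(ids)
  part <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  folds <- lapply(seq_len(k), function(i) {
    val <- if (i == k) 1L else i + 1L
    list(fold = i,
         test_ids = sort(part[[i]]),
         val_ids = sort(part[[val]]),
         train_ids = sort(unlist(part[-c(i, val)], use.names = FALSE)))
  })
  structure(folds, class = "l2c_folds", seed = seed, k = k)
}

#' Serialise / read fold splits as JSON
#'
#' @param folds An `l2c_folds` object.
#' @param path JSON path.
#' @return `path` (write) or an `l2c_folds` object (read).
#' @export
write_folds <- function(folds, path) {
  payload <- lapply(folds, function(f)
    list(fold = f$fold, train_ids = f$train_ids,
         val_ids = f$val_ids, test_ids = f$test_ids))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_folds
#' @export
read_folds <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(nrow(payload)), function(i)
    list(fold = payload$fold[i],
         train_ids = as.character(payload$train_ids[[i]]),
         val_ids = as.character(payload$val_ids[[i]]),
         test_ids = as.character(payload$test_ids[[i]])))
  structure(folds, class = "l2c_folds", k = length(folds))
}

#' First-half / second-half split of one participant's visits
#'
#' The first `ceiling(m / 2)` visits become the observed input; the remainder
#' are the forecasting targets (a 10-visit participant contributes 5 input and
#' 5 target visits; odd counts give the extra visit to the input side).
#'
#' @param visits Tibble of one participant's visits, ordered by month.
#' @return A list with tibbles `input` and `target`, both non-empty.
#' @export
split_half <- function(visits) {
  m <- nrow(visits)
  if (m < 2) stop("split_half needs at least two visits")
  n_in <- ceiling(m / 2)
  list(input = visits[seq_len(n_in), , drop = FALSE],
       target = visits[(n_in + 1):m, , drop = FALSE])
}
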