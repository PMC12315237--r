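# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a statistical test result
#'
#' @param x An `l2c_test`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, `method` and the
#'   test's size parameter (`k` folds or `n_perm` permutations).
#' @export
tidy.l2c_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 method = x$method,
                 k = x$k %||% NA_integer_,
                 rho = x$rho %||% NA_real_,
                 n_perm = x$n_perm %||% NA_integer_)
}

#' Tidy / summarise a model bundle
#'
#' `tidy()` lists the estimators (one row per target and window);
#' `glance()` gives a one-row summary.
#'
#' @param x An `l2c_bundle`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.l2c_bundle <- function(x, ...) {
  if (x$variant == "xgb_w") {
    rows <- lapply(names(x$estimators), function(tg) {
      tibble::tibble(target = tg, window = x$windows[[tg]]$label)
    })
    return(dplyr::bind_rows(rows))
  }
  if (x$variant == "xgb_nw") {
    return(tibble::tibble(target = names(x$estimators),
                          window = "all"))
  }
  tibble::tibble(target = c("diagnosis", "mmse", "ventricle"),
                 window = "all")
}

#' @rdname tidy.l2c_bundle
#' @export
glance.l2c_bundle <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 n_estimators = bundle_estimator_count(x),
                 seed = x$seed %||% NA_integer_)
}

#' Tidy / summarise an experiment
#'
#' `tidy()` returns the per-fold metric table; `glance()` aggregates the
#' main analysis to mean and SD per variant.
#'
#' @param x An `l2c_experiment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.l2c_experiment <- function(x, ...) x$metrics

#' @rdname tidy.l2c_experiment
#' @export
glance.l2c_experiment <- function(x, ...) {
  m <- x$metrics[x$metrics$analysis == "main", , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(m, .data$variant),
    n_folds = dplyr::n(),
    mauc_mean = mean(.data$mauc), mauc_sd = stats::sd(.data$mauc),
    mmse_mae_mean = mean(.data$mmse_mae),
    mmse_mae_sd = stats::sd(.data$mmse_mae),
    ventricle_mae_mean = mean(.data$ventricle_mae),
    ventricle_mae_sd = stats::sd(.data$ventricle_mae),
    .groups = "drop")
}

#' @importFrom rlang .data
NULL
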