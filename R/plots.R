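# ggplot2 displays for forecast grids, experiment reports and simulated
# cohorts.

#' Plot a monthly forecast grid
#'
#' Diagnosis-class probabilities, MMSE and ventricle/ICV trajectories over
#' the forecast horizon, one facet per task, coloured by participant.
#'
#' @param object An `l2c_forecast` from [forecast_monthly()].
#' @param participants Optional subset of participant ids.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.l2c_forecast <- function(object, participants = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(participants)) {
    df <- df[df$participant_id %in% participants, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    df, c("p_cn", "p_mci", "p_dem", "mmse", "ventricle_icv"),
    names_to = "task", values_to = "value")
  long$task <- factor(long$task,
                      levels = c("p_cn", "p_mci", "p_dem", "mmse",
                                 "ventricle_icv"),
                      labels = c("P(CN)", "P(MCI)", "P(DEM)", "MMSE",
                                 "Ventricle / ICV"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$horizon, y = .data$value,
                                     colour = .data$participant_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~task, scales = "free_y") +
    ggplot2::labs(x = "Months past last observed visit", y = NULL,
                  colour = "Participant") +
    ggplot2::theme_minimal()
}

#' Plot fold-level experiment metrics
#'
#' Boxplots of the main-analysis metric across folds, one panel per metric,
#' grouped by model variant.
#'
#' @param object An `l2c_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.l2c_experiment <- function(object, ...) {
  m <- object$metrics
  m <- m[m$analysis == "main", , drop = FALSE]
  long <- tidyr::pivot_longer(m, c("mauc", "mmse_mae", "ventricle_mae"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("mauc", "mmse_mae", "ventricle_mae"),
                        labels = c("Diagnosis mAUC", "MMSE MAE",
                                   "Ventricle MAE"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Spaghetti plot of simulated biomarker trajectories
#'
#' @param cohort Cohort tibble (e.g. from [generate_cohort()]).
#' @param biomarker Column to plot (default `"mmse"`).
#' @param n_participants Number of randomly chosen participants to show.
#' @return A ggplot object.
#' @export
plot_cohort_trajectories <- function(cohort, biomarker = "mmse",
                                     n_participants = 30) {
  ids <- unique(cohort$participant_id)
  if (length(ids) > n_participants) ids <- ids[seq_len(n_participants)]
  df <- cohort[cohort$participant_id %in% ids, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$month, y = .data[[biomarker]],
                                   group = .data$participant_id,
                                   colour = .data$diagnosis)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Months since baseline", y = biomarker,
                  colour = "Diagnosis") +
    ggplot2::theme_minimal()
}
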