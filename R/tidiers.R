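#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a fitted motion model
#'
#' @param x A [fit_motion_model()] result.
#' @param ... Unused.
#' @return Tibble with `iteration` and `cost` (MSE on normalized targets).
#' @export
tidy.motion_fit <- function(x, ...) x$history

#' One-row summary of a fitted motion model
#'
#' @param x A [fit_motion_model()] result.
#' @param ... Unused.
#' @return Tibble: family, window/horizon (samples), iterations run, final
#'   training cost, number of learnable parameters.
#' @export
glance.motion_fit <- function(x, ...) {
  tibble(
    family = x$family,
    fraction_id = x$fraction_id,
    t_delay = x$spec$t_delay,
    t_ahead = x$spec$t_ahead,
    iterations = nrow(x$history),
    final_cost = x$history$cost[nrow(x$history)],
    n_params = n_params(x$model)
  )
}

#' Tidy a grid-search result
#'
#' @param x A [grid_search()] result.
#' @param ... Unused.
#' @return The full results tibble: one row per evaluated configuration
#'   with per-fraction RMSEs and `mean_rmse`.
#' @export
tidy.grid_search_result <- function(x, ...) x$results

#' One-row summary of a grid search
#'
#' @param x A [grid_search()] result.
#' @param ... Unused.
#' @return The winning configuration with the number of configurations
#'   evaluated.
#' @export
glance.grid_search_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(family = x$family, n_configurations = nrow(x$results)),
    x$best_config
  )
}

#' Plot predicted vs true tumor traces
#'
#' One panel per anatomical direction, true and predicted positions over
#' the evaluated test range.
#'
#' @param object A `prediction_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_result <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(-c("index", "time_s"),
                        names_to = c("series", "direction"),
                        names_pattern = "(T|pred)_(SI|AP|LR)",
                        values_to = "position_mm") |>
    dplyr::mutate(
      series = ifelse(.data$series == "T", "true", "predicted"),
      direction = factor(.data$direction, levels = DIRECTIONS)
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$position_mm,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~direction, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("%s, %s (ahead %g ms)", attr(object, "fraction_id"),
                      attr(object, "model"), attr(object, "ahead_ms")),
      x = "time (s)", y = "position (mm)", colour = NULL
    )
}

#' Plot an experiment's 3D RMSE by condition
#'
#' With a single ahead time: per-fraction 3D RMSE as boxplots per condition.
#' With several ahead times: cohort-mean 3D RMSE against ahead time, one
#' line per condition.
#'
#' @param object An [run_experiment()] result.
#' @param by Condition column (default `"model"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_result <- function(object, by = "model", ...) {
  if (length(unique(object$ahead_ms)) > 1) {
    means <- object |>
      dplyr::group_by(.data[[by]], .data$ahead_ms) |>
      dplyr::summarise(rmse_3d = mean(.data$rmse_3d), .groups = "drop")
    ggplot2::ggplot(means, ggplot2::aes(.data$ahead_ms, .data$rmse_3d,
                                        colour = .data[[by]])) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "ahead time (ms)", y = "mean 3D RMSE (mm)")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data[[by]], .data$rmse_3d)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(x = NULL, y = "3D RMSE (mm)")
  }
}

#' Plot the training loss curve
#'
#' @param object A [fit_motion_model()] result.
#' @param ... Unused.
#' @return A ggplot object (log-scale cost vs iteration).
#' @export
autoplot.motion_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$iteration, .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Adam iteration", y = "training cost (MSE, normalized)")
}
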