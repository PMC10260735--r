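#' Plot a fitted time-activity curve over its data
#'
#' @param object A converged `tia_fit`.
#' @param ... Unused.
#' @return A ggplot: sampled activities as points, the fitted curve as a
#'   line over a dense time grid.
#' @export
autoplot.tia_fit <- function(object, ...) {
  if (!object$converged) stop("cannot plot a failed fit", call. = FALSE)
  grid <- tibble::tibble(
    time_h = seq(0, max(object$data$time_h) * 1.2, length.out = 200))
  grid$activity_MBq <- eval_activity(object$model, grid$time_h)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_h, y = .data$activity_MBq)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Time post-injection (h)", y = "Activity (MBq)",
                  title = sprintf("%s fit, TIA = %.4g MBq·h",
                                  object$kind, object$tia)) +
    ggplot2::theme_minimal()
}

#' Plot single-time-point error versus sampling time
#'
#' Mean percent error (with a band of one SD) as a function of the single
#' imaging time, one line per method; the minimum-RMSE time of each method is
#' marked.
#'
#' @param results STP rows from [evaluate_method()] (possibly several methods
#'   bound together).
#' @return A ggplot.
#' @export
plot_stp_error <- function(results) {
  stopifnot(all(c("method", "t1", "mpe", "sd_pe", "rmse") %in% names(results)))
  opt <- results |>
    dplyr::group_by(.data$method) |>
    dplyr::slice_min(.data$rmse, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(results, ggplot2::aes(x = .data$t1, y = .data$mpe,
                                        colour = .data$method,
                                        fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mpe - .data$sd_pe,
                                      ymax = .data$mpe + .data$sd_pe),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(data = opt, shape = 4, size = 3, stroke = 1.5) +
    ggplot2::labs(x = "Imaging time (h post-injection)",
                  y = "Mean percent error in TIA (%)",
                  colour = "Method", fill = "Method") +
    ggplot2::theme_minimal()
}

#' Heatmap of two-time-point schedule errors
#'
#' @param results 2TP rows from [evaluate_method()].
#' @param metric Column to map to fill (default mean percent error).
#' @param limit Symmetric colour limit in percent; cells beyond it are
#'   squished so a few pathological schedules do not wash out the scale.
#' @return A ggplot tile map, first imaging time on x, second on y.
#' @export
plot_pe_heatmap <- function(results, metric = "mpe", limit = 25) {
  stopifnot(all(c("t1", "t2", metric) %in% names(results)))
  df <- dplyr::mutate(
    results, value = pmax(pmin(.data[[metric]], limit), -limit))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$t2,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-limit, limit),
                                  name = paste0(metric, " (%)")) +
    ggplot2::labs(x = "First imaging time (h)", y = "Second imaging time (h)") +
    ggplot2::theme_minimal()
}
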