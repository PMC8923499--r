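#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot clock-offset functions
#'
#' Offset versus time for each receiver, one line per receiver, with the
#' solver's knots marked.
#'
#' @param object A `sync_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sync_fit
#' @export
autoplot.sync_fit <- function(object, ...) {
  m <- tibble::as_tibble(object$model)
  ggplot2::ggplot(m, ggplot2::aes(x = .data$knot_time / 3600,
                                  y = .data$offset * 1000,
                                  color = .data$receiver_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (h)", y = "clock offset (ms)",
                  color = "receiver") +
    ggplot2::theme_minimal()
}

#' Plot swimming-velocity distributions
#'
#' Weighted kernel densities of longitudinal swimming velocity, one curve
#' per vertical averaging range; negative values are positive rheotaxis.
#'
#' @param object A `swim_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot swim_summary
#' @export
autoplot.swim_summary <- function(object, ...) {
  kde <- attr(object, "kde")
  ggplot2::ggplot(kde, ggplot2::aes(x = .data$x, y = .data$density,
                                    color = .data$vrange)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "longitudinal swimming velocity (m/s)",
                  y = "density", color = "vertical range") +
    ggplot2::theme_minimal()
}

#' Target diagram of model skill
#'
#' Bias (ordinate) against signed unbiased RMSE (abscissa) for one or more
#' comparison sets; points left of center under-predict the observed
#' variance, points right of center over-predict it.
#'
#' @param metrics One or more rows from [calibration_metrics()] (bind rows
#'   and add a `label` column to compare sets).
#' @return A ggplot.
#' @export
plot_target_diagram <- function(metrics) {
  r <- max(abs(c(metrics$target_x, metrics$target_y))) * 1.2
  circ <- purrr::map_dfr(c(0.5, 1) * r, function(rr) {
    th <- seq(0, 2 * pi, length.out = 181)
    tibble::tibble(x = rr * cos(th), y = rr * sin(th), r = rr)
  })
  p <- ggplot2::ggplot(metrics,
                       ggplot2::aes(x = .data$target_x, y = .data$target_y)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$r),
                       linetype = 3, color = "grey60", inherit.aes = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "signed uRMSE (m/s)", y = "bias (m/s)") +
    ggplot2::theme_minimal()
  if ("label" %in% names(metrics)) {
    p <- p + ggplot2::aes(color = .data$label)
  }
  p
}
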