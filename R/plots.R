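# ggplot2 methods for the package's result types.

#' @method autoplot twims_calibration
#' @export
autoplot.twims_calibration <- function(object, ...) {
  cal <- object$calibrants
  ggplot2::ggplot(cal, ggplot2::aes(log(.data$t_corr_ms), log(.data$ccs_corr))) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "ln corrected arrival time (ms)",
      y = "ln corrected CCS",
      title = sprintf("T-wave calibration (r² = %.4f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot kinetics_fit
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  cur <- object$curve
  p <- ggplot2::ggplot(cur, ggplot2::aes(.data$timepoint_min, .data$pct_d)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$pct_d - .data$sd, ymax = .data$pct_d + .data$sd),
      width = 0.05
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "labelling time (min)", y = "deuteration (%)",
      title = sprintf("%s association fit", object$model)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    grid <- tibble(
      timepoint_min = exp(seq(
        log(min(cur$timepoint_min)), log(max(cur$timepoint_min)),
        length.out = 100
      ))
    )
    grid$pct_d <- predict(object$fit, newdata = list(t = grid$timepoint_min))
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}

#' @method autoplot discrimination_result
#' @export
autoplot.discrimination_result <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(
    tab, ggplot2::aes(.data$id, .data$deviation_pct, fill = .data$accepted)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = c(-1, 1) * object$threshold, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "candidate", y = "CCS deviation from experiment (%)",
      title = sprintf("best candidate: %s", object$best)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mass spectrum with optional picked peaks
#'
#' @param spectrum tibble `mz`, `intensity`.
#' @param peaks optional peak list from [pick_peaks()].
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum, peaks = NULL) {
  p <- ggplot2::ggplot(
    as_tibble(spectrum), ggplot2::aes(.data$mz, .data$intensity)
  ) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Th)", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = as_tibble(peaks), colour = "firebrick", size = 1.5
    )
  }
  p
}
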