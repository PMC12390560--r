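# ggplot2 autoplot methods for the main result types

#' @export
autoplot.emg_recording <- function(object, ...) {
  ann <- annotations(object)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s, y = .data$emg_mV)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "EMG (mV, electrode-referred)")
  if (nrow(ann) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ann,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "orange"
    )
  }
  p
}

#' @export
autoplot.boost_trace <- function(object, ...) {
  cfg <- attr(object, "cfg")
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_s", "v_out", "duty")],
    -"time_s", names_to = "variable", values_to = "value"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (!is.null(cfg)) {
    band <- tibble::tibble(variable = "v_out",
                           lo = cfg$setpoint - cfg$band,
                           hi = cfg$setpoint + cfg$band)
    p <- p + ggplot2::geom_hline(
      data = band, ggplot2::aes(yintercept = .data$lo), linetype = 2
    ) + ggplot2::geom_hline(
      data = band, ggplot2::aes(yintercept = .data$hi), linetype = 2
    )
  }
  p
}

#' @export
autoplot.waveform_set <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                            names_to = "channel", values_to = "current_mA")
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$time_s, y = .data$current_mA)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "current (mA)")
}

#' @export
autoplot.roc_detection <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}

#' @export
autoplot.latency_study <- function(object, binwidth = 0.25, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$latency_ms)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = mean(object$latency_ms),
                        linetype = 2) +
    ggplot2::labs(x = "closed-loop latency (ms)", y = "trials")
}
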