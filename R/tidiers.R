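# broom-style tidiers for the study objects

#' @export
tidy.latency_study <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("trial", "latency_ms")])
}

#' @export
glance.latency_study <- function(x, k = 5, ...) {
  n <- nrow(x)
  if (n %% k != 0) k <- 1
  latency_stats(x$latency_ms, k = max(k, 1))
}

#' @export
tidy.roc_detection <- function(x, ...) x$curve

#' @export
glance.roc_detection <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, optimal_threshold = x$optimal_threshold,
    sensitivity = x$sensitivity, specificity = x$specificity,
    n_sessions = x$n_sessions
  )
}

#' @export
glance.boost_trace <- function(x, event_time = NULL, ...) {
  cfg <- attr(x, "cfg")
  load <- attr(x, "load")
  event_time <- event_time %||%
    if (length(load$breakpoints) > 1) load$breakpoints[2] else 0
  m <- settling_metrics(x, event_time, cfg)
  tibble::add_column(m, setpoint = cfg$setpoint, .before = 1)
}
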