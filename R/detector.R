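#' Event-detector configuration
#'
#' Parameters of the real-time detection chain running on the digitized,
#' electrode-referred signal: causal moving-average smoothing, a causal
#' sliding-RMS envelope, and fixed-threshold upward-crossing detection with
#' refractory suppression. Window defaults of 5 samples (5 ms at the 1 kHz
#' ADC rate) keep the envelope delay compatible with a sub-10 ms loop
#' budget; the 0.3 mV default threshold is electrode-referred.
#'
#' @param ma_window Moving-average window, samples.
#' @param rms_window RMS window, samples.
#' @param threshold Detection threshold, mV (electrode-referred envelope).
#' @param refractory Minimum spacing between emitted events, seconds.
#' @param mode `"fixed"` threshold, or `"adaptive"` (baseline-tracking
#'   threshold, provided as an optional variant).
#'
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(ma_window = 5, rms_window = 5, threshold = 0.3,
                            refractory = 0.5, mode = c("fixed", "adaptive")) {
  mode <- match.arg(mode)
  ma_window <- check_count(ma_window, "ma_window")
  rms_window <- check_count(rms_window, "rms_window")
  check_number(threshold, "threshold", lower = 0, closed_lower = FALSE)
  check_number(refractory, "refractory", lower = 0)
  structure(
    list(ma_window = ma_window, rms_window = rms_window,
         threshold = threshold, refractory = refractory, mode = mode),
    class = "detector_config"
  )
}

causal_mean <- function(x, w) {
  n <- length(x)
  if (w == 1L || n == 0L) return(as.double(x))
  cs <- cumsum(x)
  out <- numeric(n)
  head_n <- min(w - 1L, n)
  out[seq_len(head_n)] <- cs[seq_len(head_n)] / seq_len(head_n)
  if (n >= w) {
    i <- w:n
    out[i] <- (cs[i] - c(0, cs)[i - w + 1L]) / w
  }
  out
}

#' Causal moving average
#'
#' Mean over the trailing `w` samples (shorter windows at the start of the
#' signal). Same length as the input.
#'
#' @param x Signal, mV.
#' @param w Window length in samples, >= 1.
#' @return Smoothed signal.
#' @export
moving_average <- function(x, w) {
  w <- check_count(w, "w")
  causal_mean(x, w)
}

#' Causal sliding-RMS envelope
#'
#' Root of the trailing-window mean of the squared signal; the detection
#' statistic of the trigger algorithm.
#'
#' @inheritParams moving_average
#' @return Envelope, mV (non-negative).
#' @export
rms_envelope <- function(x, w) {
  w <- check_count(w, "w")
  sqrt(pmax(causal_mean(x^2, w), 0))
}

# centered (zero-phase) variants, offline analysis only
centered_mean <- function(x, w) {
  if (w == 1L) return(as.double(x))
  k <- rep(1 / w, w)
  pad <- floor((w - 1) / 2)
  xe <- c(rep(x[1], w), x, rep(x[length(x)], w))
  out <- as.numeric(stats::filter(xe, k, sides = 2))
  out[(w + 1):(w + length(x))]
}

zero_phase_envelope <- function(x, ma_w, rms_w) {
  sqrt(pmax(centered_mean(centered_mean(x, ma_w)^2, rms_w), 0))
}

#' Threshold-crossing event detection
#'
#' Emits an event at every upward crossing of the threshold (previous sample
#' below, current sample at or above; the first sample triggers if it already
#' sits at or above threshold) and suppresses any crossing within the
#' refractory period of the last emitted event. Event time is the first
#' sample at/above threshold (sample-clocked, not interpolated), with `t = 0`
#' at the first sample.
#'
#' @param envelope Detection envelope from [rms_envelope()], mV.
#' @param fs Sampling rate of the envelope, Hz.
#' @param cfg A [detector_config()]. When `cfg$mode == "adaptive"`, the
#'   per-sample threshold from [adaptive_threshold()] replaces the fixed one.
#' @param ... Passed on to [adaptive_threshold()] in adaptive mode.
#' @return A tibble of detection events with columns `t_s` and `env_mV`.
#' @export
detect_events <- function(envelope, fs, cfg = detector_config(), ...) {
  thr <- if (cfg$mode == "adaptive") {
    adaptive_threshold(envelope, fs, ...)
  } else {
    rep_len(cfg$threshold, length(envelope))
  }
  n <- length(envelope)
  if (n == 0L) return(tibble::tibble(t_s = double(), env_mV = double()))
  above <- envelope >= thr
  crossing <- above & c(TRUE, !above[-n])
  cand <- which(crossing)
  keep <- integer(0)
  last_t <- -Inf
  for (i in cand) {
    t_i <- (i - 1) / fs
    if (t_i - last_t >= cfg$refractory) {
      keep <- c(keep, i)
      last_t <- t_i
    }
  }
  tibble::tibble(t_s = (keep - 1) / fs, env_mV = envelope[keep])
}

#' Baseline-tracking adaptive threshold
#'
#' Per-sample threshold `mean + k_sigma * sd` of a trailing baseline window,
#' where the baseline excludes samples that were at or above the running
#' threshold when they arrived (so bursts do not inflate their own
#' threshold). Provided as the optional adaptive variant of the fixed
#' detector.
#'
#' @param envelope Detection envelope, mV.
#' @param fs Sampling rate, Hz.
#' @param k_sigma Multiplier on the baseline standard deviation.
#' @param baseline_window Trailing window length in seconds.
#' @return Per-sample threshold, mV (same length as `envelope`).
#' @export
adaptive_threshold <- function(envelope, fs, k_sigma = 3,
                               baseline_window = 2) {
  check_number(k_sigma, "k_sigma", lower = 0)
  check_number(baseline_window, "baseline_window", lower = 0,
               closed_lower = FALSE)
  w <- max(2L, round(baseline_window * fs))
  n <- length(envelope)
  thr <- numeric(n)
  buf <- numeric(w)
  head_i <- 0L; count <- 0L
  s1 <- 0; s2 <- 0
  for (i in seq_len(n)) {
    if (count < 2L) {
      thr[i] <- if (count == 0L) Inf else s1 / count
    } else {
      m <- s1 / count
      v <- max((s2 - count * m^2) / (count - 1), 0)
      if (v < 1e-12 * max(s2 / count, 1)) v <- 0  # cancellation guard
      thr[i] <- m + k_sigma * sqrt(v)
    }
    x <- envelope[i]
    accept <- if (count == 0L) TRUE else x <= thr[i] || !is.finite(thr[i])
    if (count == 0L) accept <- TRUE
    if (accept) {
      head_i <- head_i %% w + 1L
      if (count == w) {
        old <- buf[head_i]
        s1 <- s1 - old; s2 <- s2 - old^2
      } else {
        count <- count + 1L
      }
      buf[head_i] <- x
      s1 <- s1 + x; s2 <- s2 + x^2
    }
  }
  thr[1] <- envelope[1]  # no history yet: threshold collapses to the sample
  thr
}
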