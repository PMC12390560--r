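# Small fixture builders shared across the suite.

one_burst_recording <- function(amplitude = 2, seed = 1, ramp_frac = 0.02,
                                baseline = 0.05, fs = 4000) {
  synthesize_emg(
    burst_spec(onset_times = 0.5, durations = 0.5,
               peak_amplitude = amplitude, ramp_frac = ramp_frac),
    noise_spec(baseline_rms = baseline),
    duration = 1.2, fs = fs, seed = seed
  )
}

# periodogram band-power fraction (oracle for spectral confinement)
band_power_fraction <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  inb <- half & freq >= band[1] & freq <= band[2]
  sum(p[inb]) / sum(p[half])
}

# least-squares sine fit at a known frequency; returns amplitude and the
# residual standard deviation
sine_fit <- function(x, t, freq) {
  s <- sin(2 * pi * freq * t); c_ <- cos(2 * pi * freq * t)
  fit <- stats::lm(x ~ s + c_)
  list(amplitude = sqrt(sum(stats::coef(fit)[c("s", "c_")]^2)),
       resid_sd = stats::sd(stats::resid(fit)))
}

# exhaustive maximal matching oracle: maximum number of one-to-one
# detection/onset pairs within tolerance (recursive search, small n only)
max_matching_oracle <- function(det, onsets, tolerance) {
  if (length(det) == 0 || length(onsets) == 0) return(0L)
  feasible <- abs(outer(det, onsets, "-")) <= tolerance
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (length(det) - i + 1) <= best) return()
    if (i > length(det)) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used, count)  # leave detection i unmatched
    for (j in which(feasible[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      recurse(i + 1L, used2, count + 1L)
    }
  }
  recurse(1L, rep(FALSE, length(onsets)), 0L)
  best
}
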