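#' Per-stage delay model of the closed loop
#'
#' Stage delays of the acquisition-to-stimulation path. These defaults are
#' calibration constants chosen to reproduce bench latency measurements of
#' the hardware loop, not quantities derived from first principles: a
#' uniform 0-1 ms ADC sampling-phase alignment, a 2.0 ms envelope-processing
#' delay attributed to the causal detector filters, a fixed 1.4 ms firmware
#' processing delay, and an output stage of 5.5 ms mean with 0.6 ms Gaussian
#' jitter (truncated at zero). Their sum gives a 9.4 ms mean latency with
#' about 0.67 ms spread.
#'
#' @param envelope_group_delay Nominal envelope (filter-chain) delay,
#'   seconds.
#' @param processing_delay Fixed decision/firmware delay, seconds.
#' @param output_stage_mean,output_stage_sd Output-stage delay distribution
#'   Normal(mean, sd), truncated at 0, seconds.
#' @param sampling_phase_max Upper bound of the uniform sampling-phase
#'   delay, seconds (one ADC period).
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(envelope_group_delay = 2.0e-3,
                         processing_delay = 1.4e-3,
                         output_stage_mean = 5.5e-3,
                         output_stage_sd = 0.6e-3,
                         sampling_phase_max = 1e-3) {
  for (nm in c("envelope_group_delay", "processing_delay",
               "output_stage_mean", "output_stage_sd",
               "sampling_phase_max")) {
    check_number(get(nm), nm, lower = 0)
  }
  structure(
    list(envelope_group_delay = envelope_group_delay,
         processing_delay = processing_delay,
         output_stage_mean = output_stage_mean,
         output_stage_sd = output_stage_sd,
         sampling_phase_max = sampling_phase_max),
    class = "timing_model"
  )
}

process_recording <- function(rec, frontend, det) {
  fs_native <- sampling_rate(rec)
  amplified <- amplify(rec$emg_mV, 0, frontend)
  filtered <- bandpass(amplified, fs_native, frontend)
  stream <- digitize(filtered, fs_native, frontend)
  mv <- codes_to_mv(stream, frontend)
  env <- rms_envelope(moving_average(mv, det$ma_window), det$rms_window)
  list(envelope = env, fs = frontend$adc_fs, mv = mv,
       duration = nrow(rec) / fs_native)
}

#' Run one closed-loop trial
#'
#' Feeds a synthetic EMG recording through the full chain -- amplifier,
#' band-pass, ADC, envelope detector -- and composes the stage delays of the
#' timing model on top of the detection instant:
#'
#' `stim_onset = detect_time + sampling_phase + envelope_delay
#'   + processing_delay + output_stage`
#'
#' The envelope-delay term is accounted once, in one of two modes:
#' `"nominal"` uses the calibrated `envelope_group_delay` constant;
#' `"measured"` uses the empirical lag between the causal detection instant
#' and the threshold crossing of a zero-phase (centered-window) envelope of
#' the same signal. Latency is `stim_onset - detect_time`, reported in ms.
#'
#' @param rec An [emg_recording][synthesize_emg()] with at least one
#'   annotated burst.
#' @param frontend A [frontend_config()].
#' @param det A [detector_config()].
#' @param timing A [timing_model()].
#' @param seed Integer seed for the delay draws.
#' @param envelope_accounting `"nominal"` or `"measured"` (see above).
#' @return A one-row tibble (`loop_result`): `truth_onset_s`,
#'   `detect_time_s`, `stim_onset_s`, `latency_ms`.
#' @export
run_trial <- function(rec, frontend = frontend_config(),
                      det = detector_config(), timing = timing_model(),
                      seed = 1L,
                      envelope_accounting = c("nominal", "measured")) {
  envelope_accounting <- match.arg(envelope_accounting)
  ann <- annotations(rec)
  if (nrow(ann) < 1) abort("`rec` must contain at least one annotated burst.")
  proc <- process_recording(rec, frontend, det)
  events <- detect_events(proc$envelope, proc$fs, det)
  if (nrow(events) == 0) {
    new_tensloop_error("no burst crossed the detection threshold",
                       "tensloop_error_nodetect")
  }
  detect_time <- events$t_s[1]

  env_delay <- if (envelope_accounting == "nominal") {
    timing$envelope_group_delay
  } else {
    zp <- zero_phase_envelope(proc$mv, det$ma_window, det$rms_window)
    zp_cross <- which(zp >= det$threshold)[1]
    if (is.na(zp_cross)) {
      new_tensloop_error("zero-phase envelope never crosses threshold",
                         "tensloop_error_nodetect")
    }
    max(detect_time - (zp_cross - 1) / proc$fs, 0)
  }

  local_seed(seed)
  sampling_phase <- runif(1, 0, timing$sampling_phase_max)
  output_delay <- max(rnorm(1, timing$output_stage_mean,
                            timing$output_stage_sd), 0)
  stim_onset <- detect_time + sampling_phase + env_delay +
    timing$processing_delay + output_delay
  tibble::tibble(
    truth_onset_s = ann$onset_s[1],
    detect_time_s = detect_time,
    stim_onset_s = stim_onset,
    latency_ms = (stim_onset - detect_time) * 1000
  )
}

latency_trial_recording <- function(seed, burst_amplitude = 2,
                                    fs = 4000) {
  synthesize_emg(
    burst_spec(onset_times = 0.5, durations = 0.5,
               peak_amplitude = burst_amplitude, ramp_frac = 0.02),
    noise_spec(baseline_rms = 0.05),
    duration = 1.2, fs = fs, seed = seed
  )
}

#' Closed-loop latency study
#'
#' Runs `n_trials` independent closed-loop trials, each with a freshly
#' synthesized single-burst recording (0.5 s burst, 2 mV plateau over a
#' 0.05 mV baseline -- a strong, cleanly detectable activation, emulating a
#' function-generator test signal) and fresh delay draws, under per-trial
#' seeds derived from `base_seed`.
#'
#' @param n_trials Number of trials (>= 2).
#' @param base_seed Integer seed for the whole study.
#' @param frontend,det,timing Configuration objects.
#' @param burst_amplitude Plateau RMS amplitude of the test burst, mV.
#' @param envelope_accounting Passed to [run_trial()].
#' @return A `latency_study`: tibble with `trial` and `latency_ms`, with the
#'   configuration stored as attributes. [glance()] gives
#'   [latency_stats()]; [tidy()] returns the trial table.
#' @export
#' @examples
#' \donttest{
#' study <- run_latency_study(n_trials = 20, base_seed = 42)
#' glance(study)
#' }
run_latency_study <- function(n_trials = 100, base_seed = 42L,
                              frontend = frontend_config(),
                              det = detector_config(),
                              timing = timing_model(),
                              burst_amplitude = 2,
                              envelope_accounting = "nominal") {
  n_trials <- check_count(n_trials, "n_trials", lower = 2L)
  lat <- vapply(seq_len(n_trials), function(i) {
    rec <- latency_trial_recording(derive_seed(base_seed, 2 * i),
                                   burst_amplitude)
    run_trial(rec, frontend, det, timing,
              seed = derive_seed(base_seed, 2 * i + 1),
              envelope_accounting = envelope_accounting)$latency_ms
  }, double(1))
  out <- tibble::tibble(trial = seq_len(n_trials), latency_ms = lat)
  structure(out, frontend = frontend, det = det, timing = timing,
            base_seed = base_seed,
            class = c("latency_study", class(out)))
}

#' Descriptive and inferential statistics of a latency sample
#'
#' Mean and SD in ms, a Shapiro-Wilk normality p-value, and a one-way
#' ANOVA p-value across `k` equal consecutive trial blocks (a
#' trial-to-trial stability check; blocks are exchangeable by construction,
#' so a healthy loop shows no block effect). Both tests are delegated to
#' the standard routines. A constant sample is flagged degenerate and gets
#' `NA` p-values with a warning.
#'
#' @param latencies Latency sample, ms (>= 3 values), or a `latency_study`.
#' @param k Number of ANOVA blocks; must divide the sample size.
#' @return A one-row tibble: `n`, `mean_ms`, `sd_ms`, `normality_p`,
#'   `anova_p`, `degenerate`.
#' @export
latency_stats <- function(latencies, k = 5) {
  if (inherits(latencies, "latency_study")) latencies <- latencies$latency_ms
  n <- length(latencies)
  if (n < 3) abort("need at least 3 latencies.")
  if (n %% k != 0) abort("`k` must divide the number of latencies.")
  degenerate <- stats::sd(latencies) == 0
  if (degenerate) {
    warn("latency sample is constant; normality/ANOVA tests inapplicable")
    norm_p <- NA_real_
    anova_p <- NA_real_
  } else {
    norm_p <- shapiro.test(latencies)$p.value
    block <- factor(rep(seq_len(k), each = n / k))
    anova_p <- summary(aov(latencies ~ block))[[1]][["Pr(>F)"]][1]
  }
  tibble::tibble(
    n = n, mean_ms = mean(latencies), sd_ms = stats::sd(latencies),
    normality_p = norm_p, anova_p = anova_p, degenerate = degenerate
  )
}

#' Render one closed-loop trial trace
#'
#' Processed envelope and the triggered stimulation current on a common
#' timeline, for plotting a representative trial.
#'
#' @inheritParams run_trial
#' @param stim A [pulse_spec()] rendered from the stimulation onset.
#' @return A tibble with `time_s`, `envelope_mV`, `stim_mA`, plus the trial
#'   result as attribute `result`.
#' @export
loop_trial_trace <- function(rec, frontend = frontend_config(),
                             det = detector_config(),
                             timing = timing_model(),
                             stim = pulse_spec(amplitude = 22,
                                               phase_width = 2e-3,
                                               frequency = 100),
                             seed = 1L) {
  res <- run_trial(rec, frontend, det, timing, seed = seed)
  proc <- process_recording(rec, frontend, det)
  t <- (seq_along(proc$envelope) - 1) / proc$fs
  stim_i <- numeric(length(t))
  if (res$stim_onset_s < max(t)) {
    stim_i <- biphasic_train(stim, proc$fs, max(t) + 1 / proc$fs,
                             onset = res$stim_onset_s)[seq_along(t)]
  }
  out <- tibble::tibble(time_s = t, envelope_mV = proc$envelope,
                        stim_mA = stim_i)
  attr(out, "result") <- res
  out
}
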