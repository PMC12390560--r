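#' Biphasic stimulation pulse program
#'
#' One channel's pulse program: rectangular charge-balanced biphasic pulses
#' delivered at `frequency`, each consisting of a leading phase of
#' `amplitude` for `phase_width`, an optional interphase gap, and a trailing
#' phase of opposite sign and equal width. The amplitude range allows the
#' bench waveform of +/-22 mA and the phase-width range admits both the
#' 20-500 us programmable span and the 2 ms bench example.
#'
#' @param amplitude Peak phase current, mA (0-25).
#' @param phase_width Single-phase duration, seconds (20 us - 2.5 ms).
#' @param interphase_gap Gap between the two phases, seconds.
#' @param frequency Pulse rate, Hz (1-100).
#' @param polarity `"cathodic-first"` (leading phase negative) or
#'   `"anodic-first"`.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(amplitude = 22, phase_width = 100e-6,
                       interphase_gap = 0, frequency = 100,
                       polarity = c("cathodic-first", "anodic-first")) {
  polarity <- match.arg(polarity)
  check_number(amplitude, "amplitude", lower = 0, upper = 25)
  check_number(phase_width, "phase_width", lower = 20e-6, upper = 2.5e-3)
  check_number(interphase_gap, "interphase_gap", lower = 0)
  check_number(frequency, "frequency", lower = 1, upper = 100)
  if (2 * phase_width + interphase_gap >= 1 / frequency) {
    abort("pulse (2 * phase_width + gap) does not fit in one period.")
  }
  structure(
    list(amplitude = amplitude, phase_width = phase_width,
         interphase_gap = interphase_gap, frequency = frequency,
         polarity = polarity),
    class = "pulse_spec"
  )
}

#' Multi-channel output-stage setup
#'
#' Channel count, per-channel resistive loads, trigger times, onset jitter,
#' and the inter-channel leakage (coupling) matrix. Leakage is modelled as
#' instantaneous resistive crosstalk: the current observed on channel *i* is
#' its own drive plus `sum_j coupling[i, j] * drive_j`. The default coupling
#' matrix is calibrated from the packaged bench isolation measurements
#' ([leakage_table()]) at a 22 mA drive, so per-victim mean leakage peaks
#' reproduce the measured table.
#'
#' @param n_channels Number of output channels.
#' @param loads Per-channel load, ohm (recycled).
#' @param coupling `n x n` matrix of dimensionless leakage fractions, zero
#'   diagonal, entries in `[0, 0.05]`. Default: calibrated matrix.
#' @param trigger_times Per-channel trigger time, seconds (recycled).
#' @param jitter_sd Standard deviation of the Gaussian onset jitter, seconds.
#' @return An object of class `channel_setup`.
#' @export
channel_setup <- function(n_channels = 6, loads = 1e4, coupling = NULL,
                          trigger_times = 1e-3, jitter_sd = 0) {
  n_channels <- check_count(n_channels, "n_channels")
  loads <- rep_len(as.double(loads), n_channels)
  if (any(loads <= 0)) abort("`loads` must be positive.")
  if (is.null(coupling)) coupling <- default_coupling(n_channels)
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == n_channels)) {
    abort("`coupling` must be an n_channels x n_channels matrix.")
  }
  if (any(diag(coupling) != 0)) abort("`coupling` must have a zero diagonal.")
  if (any(coupling < 0 | coupling > 0.05)) {
    abort("`coupling` entries must lie in [0, 0.05].")
  }
  check_number(jitter_sd, "jitter_sd", lower = 0)
  structure(
    list(n_channels = n_channels, loads = loads, coupling = coupling,
         trigger_times = rep_len(as.double(trigger_times), n_channels),
         jitter_sd = jitter_sd),
    class = "channel_setup"
  )
}

#' Packaged bench isolation measurements
#'
#' Per-channel mean and standard deviation of the peak leakage current
#' measured on idle channels (matched 10 kohm loads) while another channel
#' delivered 22 mA pulses.
#'
#' @return A tibble with columns `channel`, `mean_mA`, `sd_mA`.
#' @export
leakage_table <- function() {
  path <- system.file("extdata", "leakage_table.csv", package = "tensloop",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Calibrated leakage coupling matrix
#'
#' `coupling[i, j] = mean_mA[i] / 22` for `i != j`: driving any channel at
#' 22 mA leaves the tabulated mean peak on victim channel `i`.
#'
#' @param n_channels Number of channels (up to the 6 tabulated).
#' @param drive_mA Drive amplitude the table was measured at.
#' @return A coupling matrix.
#' @export
default_coupling <- function(n_channels = 6, drive_mA = 22) {
  tab <- leakage_table()
  if (n_channels > nrow(tab)) {
    abort("no calibration data beyond 6 channels; supply `coupling`.")
  }
  frac <- tab$mean_mA[seq_len(n_channels)] / drive_mA
  m <- matrix(rep(frac, n_channels), nrow = n_channels)
  diag(m) <- 0
  m
}

biphasic_train <- function(spec, fs, duration, onset = 0) {
  n <- round(duration * fs)
  x <- numeric(n)
  np <- round(spec$phase_width * fs)
  ng <- round(spec$interphase_gap * fs)
  lead <- if (spec$polarity == "cathodic-first") -1 else 1
  period <- 1 / spec$frequency
  k <- 0
  repeat {
    t0 <- onset + k * period
    i0 <- round(t0 * fs) + 1
    if (i0 > n) break
    i1 <- min(i0 + np - 1, n)
    x[i0:i1] <- lead * spec$amplitude
    j0 <- i0 + np + ng
    j1 <- min(j0 + np - 1, n)
    if (j0 <= n) x[j0:j1] <- -lead * spec$amplitude
    k <- k + 1
  }
  x
}

#' Render a single-channel biphasic pulse train
#'
#' @param spec A [pulse_spec()].
#' @param fs Rendering rate, Hz; must give at least 10 samples per phase.
#'   The 100 kHz default resolves the shortest 100 us phases.
#' @param duration Rendered duration, seconds.
#' @param onset Time of the first pulse, seconds.
#' @return Current trace, mA.
#' @export
generate_biphasic <- function(spec, fs = 1e5, duration, onset = 0) {
  stopifnot(inherits(spec, "pulse_spec"))
  if (fs < 10 / spec$phase_width) {
    abort("`fs` must provide at least 10 samples per phase.")
  }
  check_number(duration, "duration", lower = 0, closed_lower = FALSE)
  biphasic_train(spec, fs, duration, onset)
}

new_waveform_set <- function(mat, fs, spec, setup, driven) {
  colnames(mat) <- paste0("ch", seq_len(ncol(mat)), "_mA")
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- tibble::add_column(out,
                            time_s = (seq_len(nrow(mat)) - 1) / fs,
                            .before = 1)
  structure(out, fs = fs, spec = spec, setup = setup, driven = driven,
            class = c("waveform_set", class(out)))
}

waveform_matrix <- function(wf) {
  as.matrix(wf[, grep("^ch\\d+_mA$", names(wf)), drop = FALSE])
}

#' Render synchronized multi-channel stimulation
#'
#' Renders the selected channels with a common pulse program; each driven
#' channel's onset is its trigger time plus one Gaussian jitter draw
#' (truncated at zero), emulating small hardware timing variability.
#' Undriven channels are rendered as zero current (idle but connected).
#'
#' @param setup A [channel_setup()].
#' @param spec A [pulse_spec()] applied to every driven channel.
#' @param fs Rendering rate, Hz.
#' @param duration Rendered duration, seconds.
#' @param seed Integer seed for the jitter draws.
#' @param channels Indices of the driven channels (default: all).
#' @return A `waveform_set`: tibble with `time_s` and one `ch<i>_mA` column
#'   per channel; attributes `fs`, `spec`, `setup`, `driven`.
#' @export
render_multichannel <- function(setup, spec, fs = 1e5, duration = 0.05,
                                seed = 1L,
                                channels = seq_len(setup$n_channels)) {
  stopifnot(inherits(setup, "channel_setup"), inherits(spec, "pulse_spec"))
  if (any(setup$trigger_times < 0 | setup$trigger_times > duration)) {
    abort("`trigger_times` must lie within the rendered duration.")
  }
  local_seed(seed)
  jitter <- rnorm(setup$n_channels, 0, setup$jitter_sd)
  n <- round(duration * fs)
  mat <- matrix(0, n, setup$n_channels)
  onsets <- pmax(setup$trigger_times + jitter, 0)
  for (ch in channels) {
    mat[, ch] <- generate_biphasic(spec, fs, duration, onset = onsets[ch])
  }
  driven <- seq_len(setup$n_channels) %in% channels
  wf <- new_waveform_set(mat, fs, spec, setup, driven)
  attr(wf, "onsets") <- onsets
  wf
}

#' Apply the inter-channel leakage model
#'
#' `observed_i = driven_i + sum_j coupling[i, j] * driven_j`.
#'
#' @param wf A `waveform_set` of driven currents.
#' @param setup The [channel_setup()] carrying the coupling matrix; defaults
#'   to the one stored in `wf`.
#' @return A `waveform_set` of observed currents.
#' @export
apply_crosstalk <- function(wf, setup = attr(wf, "setup")) {
  mat <- waveform_matrix(wf)
  if (ncol(mat) != nrow(setup$coupling)) {
    abort("coupling matrix dimension does not match the channel count.")
  }
  obs <- mat + mat %*% t(setup$coupling)
  out <- new_waveform_set(obs, attr(wf, "fs"), attr(wf, "spec"), setup,
                          attr(wf, "driven"))
  attr(out, "crosstalk_applied") <- TRUE
  out
}

#' Peak leakage on idle channels
#'
#' For a waveform set with exactly one driven channel, reports the peak
#' absolute current on every channel and its fraction of the driven peak.
#'
#' @param wf A `waveform_set` (after [apply_crosstalk()]).
#' @param driven Index of the driven channel; defaults to the one recorded
#'   in the waveform set.
#' @return A tibble with `channel`, `peak_mA`, `fraction`, `driven`.
#' @export
measure_isolation <- function(wf, driven = NULL) {
  flags <- attr(wf, "driven")
  if (is.null(driven)) {
    if (sum(flags) != 1L) {
      abort("`wf` must have exactly one driven channel (or supply `driven`).")
    }
    driven <- which(flags)
  }
  mat <- waveform_matrix(wf)
  peaks <- apply(abs(mat), 2, max)
  tibble::tibble(
    channel = seq_len(ncol(mat)),
    peak_mA = as.double(peaks),
    fraction = as.double(peaks) / peaks[driven],
    driven = seq_len(ncol(mat)) == driven
  )
}

#' Replicated channel-isolation study
#'
#' Emulates the bench isolation protocol: each channel is driven in turn
#' while the others idle into matched loads; the peak leakage current on
#' every idle channel is read `n_repeats` times with additive Gaussian
#' measurement noise on the peak reads, then summarised per victim channel.
#'
#' @param setup A [channel_setup()].
#' @param spec A [pulse_spec()] for the driven channel.
#' @param fs Rendering rate, Hz.
#' @param duration Rendered duration per drive, seconds.
#' @param n_repeats Repeated reads per driven channel.
#' @param noise_sd Measurement noise on each peak read, mA.
#' @param seed Integer seed.
#' @return A tibble with `channel`, `mean_mA`, `sd_mA` (victim-channel
#'   summaries, comparable to [leakage_table()]).
#' @export
isolation_study <- function(setup = channel_setup(), spec = pulse_spec(),
                            fs = 1e5, duration = 0.03, n_repeats = 10,
                            noise_sd = 0.02, seed = 1L) {
  reads <- purrr::map_dfr(seq_len(setup$n_channels), function(drv) {
    wf <- render_multichannel(setup, spec, fs, duration,
                              seed = derive_seed(seed, drv),
                              channels = drv)
    wf <- apply_crosstalk(wf)
    iso <- measure_isolation(wf, driven = drv)
    idle <- iso[!iso$driven, ]
    local_seed(derive_seed(seed, 1000 + drv))
    purrr::map_dfr(seq_len(n_repeats), function(rep) {
      tibble::tibble(
        channel = idle$channel,
        read_mA = pmax(idle$peak_mA + rnorm(nrow(idle), 0, noise_sd), 0),
        rep = rep
      )
    })
  })
  out <- dplyr::summarise(
    dplyr::group_by(reads, .data$channel),
    mean_mA = mean(.data$read_mA), sd_mA = stats::sd(.data$read_mA),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$channel)
}

#' Compliance-voltage check
#'
#' The output stage is an idealized current source; whether a pulse program
#' is actually deliverable depends on the supply. By Ohm's law the source
#' must hold `required_voltage = amplitude * load` across the electrode
#' load; the program is compliant when that does not exceed the supply.
#' Note the bench waveform of 22 mA into 10 kohm implies 220 V, beyond a
#' 100 V supply -- this check makes such inconsistencies visible instead of
#' silently clipping.
#'
#' @param spec A [pulse_spec()].
#' @param load Electrode load, ohm.
#' @param v_supply Available compliance voltage, V.
#' @return A one-row tibble with `required_voltage` (V) and `compliant`.
#' @export
check_compliance <- function(spec, load, v_supply = 100) {
  check_number(load, "load", lower = 0, closed_lower = FALSE)
  required <- spec$amplitude / 1000 * load
  tibble::tibble(required_voltage = required,
                 compliant = required <= v_supply)
}
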