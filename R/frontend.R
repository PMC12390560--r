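#' Analog front-end and ADC configuration
#'
#' Parameters of the acquisition chain: an instrumentation amplifier with
#' finite common-mode rejection, an active band-pass (Sallen-Key topology,
#' realised digitally as two cascaded Butterworth biquads), and a 12-bit ADC
#' sampling at 1 kHz behind a mid-supply virtual ground (bipolar
#' `c(-vref/2, +vref/2)` input range).
#'
#' @param gain Differential gain, V/V.
#' @param cmrr_db Common-mode rejection ratio in dB; `Inf` for an ideal
#'   amplifier.
#' @param band_low,band_high Band-pass corner frequencies in Hz.
#' @param adc_bits ADC resolution in bits (8-24).
#' @param adc_fs ADC sampling rate in Hz.
#' @param adc_vref ADC full-scale reference in volts.
#'
#' @return An object of class `frontend_config`.
#' @export
frontend_config <- function(gain = 100, cmrr_db = 80, band_low = 20,
                            band_high = 500, adc_bits = 12, adc_fs = 1000,
                            adc_vref = 3.3) {
  check_number(gain, "gain", lower = 0, closed_lower = FALSE)
  if (!identical(cmrr_db, Inf)) check_number(cmrr_db, "cmrr_db", lower = 0)
  check_number(band_low, "band_low", lower = 0, closed_lower = FALSE)
  if (band_high <= band_low) abort("`band_high` must exceed `band_low`.")
  adc_bits <- check_count(adc_bits, "adc_bits", lower = 8L)
  if (adc_bits > 24) abort("`adc_bits` must be in [8, 24].")
  check_number(adc_fs, "adc_fs", lower = 0, closed_lower = FALSE)
  check_number(adc_vref, "adc_vref", lower = 0, closed_lower = FALSE)
  structure(
    list(gain = gain, cmrr_db = cmrr_db, band_low = band_low,
         band_high = band_high, adc_bits = adc_bits, adc_fs = adc_fs,
         adc_vref = adc_vref),
    class = "frontend_config"
  )
}

#' Instrumentation-amplifier model
#'
#' `out = gain * differential + (gain / 10^(cmrr_db/20)) * common_mode`.
#' The common-mode term is the residual that a finite CMRR lets through,
#' referred to the output.
#'
#' @param differential Differential input, mV.
#' @param common_mode Common-mode input, mV (scalar or same length).
#' @param cfg A [frontend_config()].
#' @return Amplified signal, mV.
#' @export
amplify <- function(differential, common_mode = 0, cfg = frontend_config()) {
  if (length(common_mode) == 1L) {
    common_mode <- rep_len(common_mode, length(differential))
  }
  if (length(common_mode) != length(differential)) {
    abort("`differential` and `common_mode` must have equal lengths.")
  }
  cm_gain <- if (is.infinite(cfg$cmrr_db)) 0 else cfg$gain / 10^(cfg$cmrr_db / 20)
  cfg$gain * differential + cm_gain * common_mode
}

frontend_biquads <- function(cfg, rate) {
  list(
    hp = signal::butter(2, cfg$band_low / (rate / 2), type = "high"),
    lp = signal::butter(2, cfg$band_high / (rate / 2), type = "low")
  )
}

#' Band-pass filter of the acquisition front-end
#'
#' Discrete-time equivalent of the second-order Sallen-Key band-pass: one
#' Butterworth (Q = 0.707) high-pass biquad at `band_low` cascaded with one
#' Butterworth low-pass biquad at `band_high`, designed by the bilinear
#' transform with prewarped corners. Filtering is causal by default because
#' closed-loop latency must include real group delay; zero-phase filtering is
#' available for offline analysis only.
#'
#' @param x Input signal, mV.
#' @param rate Sampling rate of `x` in Hz; must exceed `2 * band_high`.
#' @param cfg A [frontend_config()].
#' @param zero_phase Use forward-backward filtering (offline use only).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, rate, cfg = frontend_config(), zero_phase = FALSE) {
  if (rate <= 2 * cfg$band_high) {
    new_tensloop_error(
      sprintf("rate %g Hz violates Nyquist for band_high = %g Hz",
              rate, cfg$band_high),
      "tensloop_error_nyquist"
    )
  }
  bq <- frontend_biquads(cfg, rate)
  apply_f <- if (zero_phase) {
    function(f, s) signal::filtfilt(f, s)
  } else {
    function(f, s) as.numeric(signal::filter(f, s))
  }
  apply_f(bq$lp, apply_f(bq$hp, x))
}

#' Designed front-end transfer function
#'
#' Complex frequency response of the band-pass cascade at given frequencies,
#' evaluated from the designed coefficients. Serves as the oracle for gain
#' and group-delay checks.
#'
#' @param freq Frequencies in Hz.
#' @inheritParams bandpass
#' @return Complex response values.
#' @export
frontend_response <- function(freq, rate, cfg = frontend_config()) {
  bq <- frontend_biquads(cfg, rate)
  w <- 2 * pi * freq / rate
  h <- function(f) {
    num <- outer(w, 0:(length(f$b) - 1), function(wi, k) exp(-1i * wi * k)) %*% f$b
    den <- outer(w, 0:(length(f$a) - 1), function(wi, k) exp(-1i * wi * k)) %*% f$a
    as.complex(num / den)
  }
  h(bq$hp) * h(bq$lp)
}

#' Group delay of the front-end band-pass
#'
#' Computed as the negative phase slope of the designed transfer function at
#' `freq`. This is the single source of truth consumed by the closed-loop
#' timing model when attributing analog-filter delay.
#'
#' @inheritParams frontend_response
#' @param freq Frequency in Hz at which the delay is evaluated.
#' @return Group delay in seconds.
#' @export
frontend_group_delay <- function(cfg = frontend_config(), rate = 4000,
                                 freq = 100) {
  df <- 1e-3 * freq
  h <- frontend_response(c(freq - df, freq + df), rate, cfg)
  dphi <- Arg(h[2] / h[1])
  -dphi / (2 * pi * (2 * df))
}

anti_alias_filter <- function(cfg, native_rate) {
  signal::butter(6, (0.45 * cfg$adc_fs) / (native_rate / 2), type = "low")
}

#' Digitize an amplified signal
#'
#' Models the ADC stage: a 6th-order Butterworth anti-alias low-pass at
#' `0.45 * adc_fs`, integer-factor decimation to `adc_fs`, and rounding
#' quantization to `adc_bits` codes over the bipolar range
#' `c(-vref/2, +vref/2)`, clamped at the rails. Codes are unsigned with
#' midscale `2^(adc_bits-1)` representing 0 V.
#'
#' @param x Amplified signal in mV (post-gain).
#' @param native_rate Sampling rate of `x` in Hz; must be an integer multiple
#'   of `adc_fs`.
#' @param cfg A [frontend_config()].
#' @return An `adc_stream`: tibble with `time_s` and `code`, plus attributes
#'   `fs`, `lsb_volts` and `origin_shift` (anti-alias group delay at 100 Hz,
#'   for delay bookkeeping).
#' @export
digitize <- function(x, native_rate, cfg = frontend_config()) {
  m <- native_rate / cfg$adc_fs
  if (abs(m - round(m)) > 1e-9) {
    abort(sprintf("native_rate (%g) must be an integer multiple of adc_fs (%g).",
                  native_rate, cfg$adc_fs))
  }
  m <- as.integer(round(m))
  origin_shift <- 0
  if (m > 1L) {
    aa <- anti_alias_filter(cfg, native_rate)
    x <- as.numeric(signal::filter(aa, x))
    # phase slope of the AA filter at 100 Hz, seconds
    w <- 2 * pi * c(99, 101) / native_rate
    hh <- vapply(w, function(wi) {
      num <- sum(aa$b * exp(-1i * wi * (0:(length(aa$b) - 1))))
      den <- sum(aa$a * exp(-1i * wi * (0:(length(aa$a) - 1))))
      num / den
    }, complex(1))
    origin_shift <- -Arg(hh[2] / hh[1]) / (2 * pi * 2)
    x <- x[seq(1L, length(x), by = m)]
  }
  lsb <- cfg$adc_vref / 2^cfg$adc_bits
  mid <- 2^(cfg$adc_bits - 1)
  codes <- round((x / 1000) / lsb) + mid
  codes <- pmin(pmax(codes, 0), 2^cfg$adc_bits - 1)
  out <- tibble::tibble(
    time_s = (seq_along(codes) - 1) / cfg$adc_fs,
    code = as.integer(codes)
  )
  structure(out, fs = cfg$adc_fs, lsb_volts = lsb, origin_shift = origin_shift,
            class = c("adc_stream", class(out)))
}

#' Convert ADC codes back to electrode-referred millivolts
#'
#' `(code - midscale) * lsb_volts / gain`, expressed in mV. Undoing the
#' amplifier gain keeps detector thresholds electrode-referred, so the
#' 0.3 mV default threshold is stated in the same units as the skin signal.
#'
#' @param stream An `adc_stream` from [digitize()], or a bare integer code
#'   vector.
#' @param cfg A [frontend_config()].
#' @return Electrode-referred signal, mV.
#' @export
codes_to_mv <- function(stream, cfg = frontend_config()) {
  codes <- if (is.data.frame(stream)) stream$code else stream
  lsb <- attr(stream, "lsb_volts") %||% (cfg$adc_vref / 2^cfg$adc_bits)
  mid <- 2^(cfg$adc_bits - 1)
  (codes - mid) * lsb * 1000 / cfg$gain
}
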