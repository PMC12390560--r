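#' Score detections against ground-truth onsets
#'
#' Matches detections to annotated onsets by greedy nearest matching: all
#' detection/onset pairs within `tolerance` are ranked by absolute time
#' difference and matched one-to-one in that order. Matched detections are
#' true positives, unmatched onsets false negatives, unmatched detections
#' false positives. Specificity is defined over non-burst decision windows:
#' the baseline (the recording minus each burst interval padded by
#' `tolerance`) is tiled with decision windows spanning `2 * tolerance` --
#' the same span the `+/- tolerance` matching rule grants a true onset, so
#' a detector firing at random scores chance level (the ROC diagonal) --
#' and a window counts as a true negative when it contains no detection.
#'
#' @param detections A tibble with a `t_s` column (e.g. from
#'   [detect_events()]), or a list of them (one per session).
#' @param truth A tibble with `onset_s` and `offset_s` columns (e.g. from
#'   [annotations()]), or a list matching `detections`.
#' @param duration Recording duration in seconds (vector for lists).
#' @param tolerance Matching tolerance, seconds.
#' @return A one-row tibble: `sensitivity`, `specificity`, `tp`, `fp`,
#'   `fn`, `tn`, `n_windows`. With empty truth, sensitivity is `NA` and a
#'   warning is raised.
#' @export
score_detections <- function(detections, truth, duration, tolerance = 0.1) {
  check_number(tolerance, "tolerance", lower = 0, closed_lower = FALSE)
  if (is.data.frame(detections)) detections <- list(detections)
  if (is.data.frame(truth)) truth <- list(truth)
  stopifnot(length(detections) == length(truth),
            length(duration) %in% c(1L, length(truth)))
  duration <- rep_len(duration, length(truth))

  counts <- purrr::pmap(list(detections, truth, duration),
                        score_one_session, tolerance = tolerance)
  tot <- purrr::reduce(counts, function(a, b) purrr::map2(a, b, `+`))
  n_onsets <- tot$tp + tot$fn
  if (n_onsets == 0) {
    warn("no annotated onsets: sensitivity is undefined")
    sens <- NA_real_
  } else {
    sens <- tot$tp / n_onsets
  }
  spec <- if (tot$n_windows > 0) tot$tn / tot$n_windows else NA_real_
  tibble::tibble(sensitivity = sens, specificity = spec,
                 tp = tot$tp, fp = tot$fp, fn = tot$fn, tn = tot$tn,
                 n_windows = tot$n_windows)
}

score_one_session <- function(det, tru, duration, tolerance) {
  dt <- det$t_s
  on <- tru$onset_s
  m <- match_greedy(dt, on, tolerance)
  tp <- length(m$det)
  fp <- length(dt) - tp
  fn <- length(on) - tp

  # non-burst decision windows
  pad_on <- pmax(tru$onset_s - tolerance, 0)
  pad_off <- pmin(tru$offset_s + tolerance, duration)
  segs <- baseline_segments(pad_on, pad_off, duration)
  tn <- 0L; n_windows <- 0L
  win <- 2 * tolerance  # same span as the +/- tolerance matching rule
  for (i in seq_len(nrow(segs))) {
    len <- segs$end[i] - segs$start[i]
    nw <- floor(len / win)
    if (nw < 1) next
    inside <- dt[dt >= segs$start[i] & dt < segs$start[i] + nw * win]
    hit_idx <- unique(floor((inside - segs$start[i]) / win))
    n_windows <- n_windows + nw
    tn <- tn + nw - length(hit_idx)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn, n_windows = n_windows)
}

match_greedy <- function(det, onsets, tolerance) {
  if (length(det) == 0 || length(onsets) == 0) {
    return(list(det = integer(0), onset = integer(0)))
  }
  d <- abs(outer(det, onsets, "-"))
  pairs <- which(d <= tolerance, arr.ind = TRUE)
  if (nrow(pairs) == 0) return(list(det = integer(0), onset = integer(0)))
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_d <- logical(length(det)); used_o <- logical(length(onsets))
  md <- integer(0); mo <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!used_d[i] && !used_o[j]) {
      used_d[i] <- TRUE; used_o[j] <- TRUE
      md <- c(md, i); mo <- c(mo, j)
    }
  }
  list(det = md, onset = mo)
}

baseline_segments <- function(starts, ends, duration) {
  if (length(starts) == 0) {
    return(tibble::tibble(start = 0, end = duration))
  }
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  seg_start <- c(0, ends)
  seg_end <- c(starts, duration)
  keep <- seg_end > seg_start
  tibble::tibble(start = seg_start[keep], end = seg_end[keep])
}

#' ROC analysis of the threshold detector on a benchmark
#'
#' Sweeps the detection threshold across the observed envelope range
#' (50 log-spaced values by default), runs the full front-end and detector
#' chain on every session at each threshold, pools counts across sessions,
#' and summarises the receiver operating characteristic. AUC is computed by
#' the trapezoid rule with endpoint anchoring at (0,0) and (1,1); the
#' optimal threshold maximises the Youden index `J = sens + spec - 1`.
#'
#' @param recordings A list of [emg_recording][synthesize_emg()]s (e.g.
#'   from [generate_benchmark()]).
#' @param frontend A [frontend_config()].
#' @param det A [detector_config()]; its threshold is overridden by the
#'   sweep.
#' @param thresholds Optional explicit threshold sweep, mV; sorted (with a
#'   warning) if not monotone.
#' @param n_thresholds Sweep length when `thresholds` is `NULL`.
#' @param tolerance Matching tolerance, seconds.
#' @param refractory Refractory period used while sweeping, seconds. The
#'   default disables it: the ROC characterises the decision statistic
#'   (envelope versus threshold), whereas the refractory is an actuation
#'   policy -- with it enabled, low thresholds let baseline noise capture
#'   the refractory window and mask true onsets, which inverts the
#'   low-threshold limb of the curve instead of driving it towards (1, 1).
#' @return A `roc_detection` object: `curve` (tibble of threshold,
#'   sensitivity, specificity, fpr), `auc`, `optimal_threshold`,
#'   `sensitivity`/`specificity` at the optimum, `n_sessions`.
#'   [tidy()] returns the curve; [glance()] a one-row summary.
#' @export
roc_detection <- function(recordings, frontend = frontend_config(),
                          det = detector_config(), thresholds = NULL,
                          n_thresholds = 50, tolerance = 0.1,
                          refractory = 0) {
  if (is.data.frame(recordings)) recordings <- list(recordings)
  proc <- purrr::map(recordings, function(rec) {
    p <- process_recording(rec, frontend, det)
    list(envelope = p$envelope, fs = p$fs, truth = annotations(rec),
         duration = p$duration)
  })
  if (is.null(thresholds)) {
    # Sweep floor at the lower quartile of the pooled envelope: below the
    # envelope's bulk an upward-crossing trigger cannot re-arm (the signal
    # rarely dips under the threshold), so those thresholds are degenerate
    # operating points, not part of the characterisable range.
    env_all <- unlist(purrr::map(proc, "envelope"))
    lo <- max(stats::quantile(env_all[env_all > 0], 0.25), 1e-6)
    hi <- max(env_all)
    thresholds <- exp(seq(log(lo), log(hi), length.out = n_thresholds))
  } else {
    if (is.unsorted(thresholds)) {
      warn("`thresholds` is not monotone; sorting")
      thresholds <- sort(thresholds)
    }
    if (length(thresholds) < 2) abort("need at least 2 thresholds.")
  }

  curve <- purrr::map_dfr(thresholds, function(thr) {
    cfg_t <- det
    cfg_t$threshold <- thr
    cfg_t$refractory <- refractory
    dets <- purrr::map(proc, ~ detect_events(.x$envelope, .x$fs, cfg_t))
    sc <- score_detections(dets, purrr::map(proc, "truth"),
                           purrr::map_dbl(proc, "duration"), tolerance)
    tibble::tibble(threshold = thr, sensitivity = sc$sensitivity,
                   specificity = sc$specificity)
  })
  curve$fpr <- 1 - curve$specificity
  auc <- auc_trapezoid(curve$fpr, curve$sensitivity)
  j <- curve$sensitivity + curve$specificity - 1
  best <- which.max(j)
  structure(
    list(curve = curve, auc = auc,
         optimal_threshold = curve$threshold[best],
         sensitivity = curve$sensitivity[best],
         specificity = curve$specificity[best],
         n_sessions = length(recordings), tolerance = tolerance),
    class = "roc_detection"
  )
}

# trapezoid AUC with (0,0)/(1,1) anchoring
auc_trapezoid <- function(fpr, tpr) {
  ok <- is.finite(fpr) & is.finite(tpr)
  fpr <- c(0, fpr[ok], 1)
  tpr <- c(0, tpr[ok], 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' @export
print.roc_detection <- function(x, ...) {
  cat(sprintf(
    paste0("<roc_detection: %d sessions, AUC %.3f>\n",
           "  optimal threshold %.4g mV: sensitivity %.1f%%, ",
           "specificity %.1f%%\n"),
    x$n_sessions, x$auc, x$optimal_threshold,
    100 * x$sensitivity, 100 * x$specificity
  ))
  invisible(x)
}

#' Battery and power model of the stimulator
#'
#' @param battery_capacity Capacity, mAh.
#' @param battery_voltage Nominal cell voltage, V.
#' @param active_current Current draw while stimulating, mA (worst-case
#'   default 95, measured range 80-95 under full six-channel load).
#' @param idle_current Current draw while idle, mA.
#' @param duty Fraction of time stimulation is active.
#' @return An object of class `power_model`.
#' @export
power_model <- function(battery_capacity = 400, battery_voltage = 3.7,
                        active_current = 95, idle_current = 0, duty = 1) {
  check_number(battery_capacity, "battery_capacity", lower = 0,
               closed_lower = FALSE)
  check_number(battery_voltage, "battery_voltage", lower = 0,
               closed_lower = FALSE)
  check_number(active_current, "active_current", lower = 0)
  check_number(idle_current, "idle_current", lower = 0)
  check_number(duty, "duty", lower = 0, upper = 1)
  structure(
    list(battery_capacity = battery_capacity,
         battery_voltage = battery_voltage,
         active_current = active_current, idle_current = idle_current,
         duty = duty),
    class = "power_model"
  )
}

#' Projected battery runtime
#'
#' `hours = capacity / effective_current` with
#' `effective_current = duty * active + (1 - duty) * idle`.
#'
#' @param model A [power_model()].
#' @return Runtime in hours.
#' @export
battery_runtime <- function(model) {
  eff <- model$duty * model$active_current +
    (1 - model$duty) * model$idle_current
  if (eff <= 0) {
    new_tensloop_error("effective current is zero: runtime undefined",
                       "tensloop_error_power")
  }
  model$battery_capacity / eff
}

#' Idle current implied by a duty-cycle power target
#'
#' Solves `duty * active + (1 - duty) * idle = target_effective` for the
#' idle current.
#'
#' @param active Active current, mA.
#' @param duty Stimulation duty fraction (< 1).
#' @param target_effective Target average current, mA.
#' @return Idle current in mA; a negative solution raises an error (the
#'   inputs are inconsistent).
#' @export
implied_idle_current <- function(active, duty, target_effective) {
  check_number(duty, "duty", lower = 0, upper = 1, closed_upper = FALSE)
  idle <- (target_effective - duty * active) / (1 - duty)
  if (idle < 0) {
    new_tensloop_error(
      "inconsistent inputs: implied idle current is negative",
      "tensloop_error_power"
    )
  }
  idle
}

#' Design of the paired-comparison study
#'
#' @param effect_size_d Cohen's d of the paired difference.
#' @param alpha Significance level.
#' @param power Target statistical power.
#' @param tails `"one"` or `"two"`.
#' @return An object of class `study_design`.
#' @export
study_design <- function(effect_size_d = 0.6, alpha = 0.05, power = 0.8,
                         tails = c("one", "two")) {
  tails <- match.arg(tails)
  check_number(effect_size_d, "effect_size_d", lower = 0,
               closed_lower = FALSE)
  check_number(alpha, "alpha", lower = 0, upper = 1, closed_lower = FALSE,
               closed_upper = FALSE)
  check_number(power, "power", lower = 0, upper = 1, closed_lower = FALSE,
               closed_upper = FALSE)
  structure(list(effect_size_d = effect_size_d, alpha = alpha,
                 power = power, tails = tails),
            class = "study_design")
}

#' Sample size for a paired two-condition comparison
#'
#' Normal-approximation formula
#' `n = ceil(((z_{1-alpha[/2]} + z_{power}) / d)^2)` for a within-subject
#' crossover comparison. The normal approximation (rather than the
#' iterative t-based calculation, which gives one to two participants more)
#' is used deliberately; see the methods vignette.
#'
#' @param design A [study_design()].
#' @return Required number of participants (integer).
#' @export
sample_size_paired <- function(design = study_design()) {
  a <- if (design$tails == "two") design$alpha / 2 else design$alpha
  z <- qnorm(1 - a) + qnorm(design$power)
  as.integer(ceiling((z / design$effect_size_d)^2))
}

#' Root mean square of successive differences
#'
#' Time-domain heart-rate-variability statistic over a series of inter-beat
#' (RR) intervals.
#'
#' @param rr_intervals RR intervals, ms (at least 2).
#' @return RMSSD in ms.
#' @export
rmssd <- function(rr_intervals) {
  if (length(rr_intervals) < 2) abort("need at least 2 RR intervals.")
  sqrt(mean(diff(rr_intervals)^2))
}

#' Normalize a physiological signal to its leading baseline
#'
#' `(x - baseline_mean) / baseline_mean`, with the baseline mean taken over
#' the leading `baseline_window` seconds. Used to express autonomic
#' responses (HRV, skin conductance) as fractional change from each
#' participant's own baseline.
#'
#' @param x Signal (any units).
#' @param baseline_window Leading window length, seconds (shorter than the
#'   signal).
#' @param fs Sampling rate, Hz.
#' @return Dimensionless normalized signal.
#' @export
normalize_to_baseline <- function(x, baseline_window, fs) {
  nb <- round(baseline_window * fs)
  if (nb < 1 || nb >= length(x)) {
    abort("`baseline_window` must be shorter than the signal and non-empty.")
  }
  m <- mean(x[seq_len(nb)])
  if (m == 0) {
    new_tensloop_error("baseline mean is zero: normalization undefined",
                       "tensloop_error_baseline")
  }
  (x - m) / m
}
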