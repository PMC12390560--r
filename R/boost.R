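#' Boost-converter plant parameters
#'
#' Physical constants of the averaged continuous-conduction boost model that
#' steps the 3.7 V battery up to a programmable output of up to 100 V.
#' Defaults describe a compact high-voltage boost stage sized so the voltage
#' loop is well damped under the stock PI gains: 100 uH power inductor with
#' 0.1 ohm winding resistance and a 100 uF output capacitor. Switching-ripple
#' detail is deliberately absent: the model is envelope-level, with PWM
#' represented by the continuous duty variable.
#'
#' @param v_in Battery input voltage, V.
#' @param inductance Inductance, H.
#' @param capacitance Output capacitance, F.
#' @param esr Output-capacitor equivalent series resistance, ohm (appears in
#'   the measured output voltage).
#' @param r_l Inductor series (winding) resistance, ohm; the dominant
#'   damping term of the averaged model.
#' @param duty_max Maximum duty cycle (must exceed `1 - v_in/setpoint` for
#'   the setpoint to be reachable).
#' @param divider_ratio Feedback divider scaling (bookkeeping only; the
#'   divider is modelled as exact, so control error is expressed in output
#'   volts).
#'
#' @return An object of class `plant_params`.
#' @export
plant_params <- function(v_in = 3.7, inductance = 100e-6,
                         capacitance = 100e-6, esr = 0.05, r_l = 0.1,
                         duty_max = 0.97, divider_ratio = 1 / 41) {
  for (nm in c("v_in", "inductance", "capacitance", "duty_max",
               "divider_ratio")) {
    check_number(get(nm), nm, lower = 0, closed_lower = FALSE)
  }
  check_number(esr, "esr", lower = 0)
  check_number(r_l, "r_l", lower = 0)
  if (duty_max >= 1) abort("`duty_max` must be < 1.")
  structure(
    list(v_in = v_in, inductance = inductance, capacitance = capacitance,
         esr = esr, r_l = r_l, duty_max = duty_max,
         divider_ratio = divider_ratio),
    class = "plant_params"
  )
}

#' PI-controller configuration
#'
#' Discrete proportional-integral voltage loop as implemented in
#' sample-clocked firmware: at each control update the integrator
#' accumulates the raw error (volt-updates at `update_rate`), and
#' `duty = kp * error + ki * integrator`, clamped to `[0, duty_max]` with
#' conditional-integration anti-windup (the integrator holds while the
#' actuator is saturated against the error sign). `kp` is therefore duty per
#' volt and `ki` duty per volt-update; the stock gains `kp = 0.15`,
#' `ki = 0.02` are usable as printed only in this per-update form.
#'
#' @param kp Proportional gain, duty per volt of error.
#' @param ki Integral gain, duty per volt-update.
#' @param setpoint Output-voltage setpoint, V (at most 100).
#' @param band Settling-band half-width, V.
#' @param update_rate Controller update rate, Hz.
#' @param integrator_limit Bound on the integral duty contribution
#'   `|ki * integrator|`, duty units.
#'
#' @return An object of class `pi_config`.
#' @export
pi_config <- function(kp = 0.15, ki = 0.02, setpoint, band = 2.5,
                      update_rate = 10000, integrator_limit = 1) {
  check_number(kp, "kp", lower = 0)
  check_number(ki, "ki", lower = 0)
  check_number(setpoint, "setpoint", lower = 0, upper = 100,
               closed_lower = FALSE)
  check_number(band, "band", lower = 0, closed_lower = FALSE)
  check_number(update_rate, "update_rate", lower = 0, closed_lower = FALSE)
  check_number(integrator_limit, "integrator_limit", lower = 0,
               closed_lower = FALSE)
  structure(
    list(kp = kp, ki = ki, setpoint = setpoint, band = band,
         update_rate = update_rate, integrator_limit = integrator_limit),
    class = "pi_config"
  )
}

#' Piecewise-constant resistive load profile
#'
#' @param breakpoints Start times in seconds of each load segment; the first
#'   must be 0 and times must be increasing.
#' @param resistances Load resistance of each segment, ohm (within
#'   100 ohm - 1 Mohm, spanning the 500 ohm - 10 kohm tissue-impedance
#'   range with margin).
#' @return An object of class `load_profile`.
#' @export
load_profile <- function(breakpoints = 0, resistances = 1e4) {
  if (length(breakpoints) != length(resistances)) {
    abort("`breakpoints` and `resistances` must have the same length.")
  }
  if (breakpoints[1] != 0) abort("the first breakpoint must be 0.")
  if (length(breakpoints) > 1 && any(diff(breakpoints) <= 0)) {
    abort("`breakpoints` must be increasing.")
  }
  if (any(resistances < 100 | resistances > 1e6)) {
    abort("`resistances` must lie within [100, 1e6] ohm.")
  }
  structure(list(breakpoints = as.double(breakpoints),
                 resistances = as.double(resistances)),
            class = "load_profile")
}

#' Convenience single-step load profile
#'
#' @param from,to Resistances before and after the step, ohm.
#' @param at Step time, seconds.
#' @return A [load_profile()].
#' @export
load_step <- function(from = 1e4, to = 500, at = 0.05) {
  load_profile(c(0, at), c(from, to))
}

#' One update of the discrete PI controller
#'
#' Reference R implementation of the firmware control law (the simulation
#' core applies the identical logic). The integrator accumulates the raw
#' error per update, bounded so the integral duty contribution stays within
#' `integrator_limit`; conditional-integration anti-windup holds the
#' integrator whenever the clamped duty is saturated against the error sign.
#'
#' @param error Voltage error `setpoint - v_out`, V.
#' @param integrator Integrator state, volt-updates.
#' @param cfg A [pi_config()].
#' @param duty_max Actuator upper clamp.
#' @return A list with `duty` and the updated `integrator`.
#' @export
pi_step <- function(error, integrator, cfg, duty_max = 0.97) {
  s_lim <- if (cfg$ki > 0) cfg$integrator_limit / cfg$ki else Inf
  s2 <- min(max(integrator + error, -s_lim), s_lim)
  duty <- min(max(cfg$kp * error + cfg$ki * s2, 0), duty_max)
  if ((duty >= duty_max && error > 0) || (duty <= 0 && error < 0)) {
    s2 <- integrator
  }
  list(duty = duty, integrator = s2)
}

#' Simulate the PI-controlled boost converter
#'
#' Integrates the averaged continuous-conduction boost model
#' `dI/dt = (v_in - r_l I - (1-d) V)/L`, `dV/dt = ((1-d) I - v/R)/C` with
#' classical RK4 at `dt_sim`, updating the duty cycle at the controller rate
#' via the discrete PI law. Inductor current is floored at zero
#' (discontinuous-conduction guard) and the run aborts with a diagnostic if
#' `|v_out|` exceeds ten times the setpoint.
#'
#' @param plant A [plant_params()].
#' @param cfg A [pi_config()].
#' @param load A [load_profile()].
#' @param duration Simulated time, seconds.
#' @param dt_sim Integration step, seconds (at most one control period).
#' @param v0,i0 Initial capacitor voltage (defaults to `v_in`) and inductor
#'   current.
#' @param duty_fixed Optional fixed duty cycle. When supplied the PI loop is
#'   bypassed and the plant runs open loop -- the characterisation mode used
#'   to verify the continuous-conduction equilibrium `v/v_in = 1/(1-d)`.
#' @return A `boost_trace`: tibble with columns `time_s`, `v_out`, `i_l`,
#'   `duty`, `load_ohm` sampled at the controller rate, with the `plant`,
#'   `cfg` and `load` stored as attributes.
#' @export
#' @examples
#' tr <- simulate_boost(plant_params(), pi_config(setpoint = 80),
#'                      load_step(1e4, 500, at = 0.05), duration = 0.2)
#' settling_metrics(tr, event_time = 0.05, pi_config(setpoint = 80))
simulate_boost <- function(plant, cfg, load = load_profile(),
                           duration = 0.2, dt_sim = 1e-6,
                           v0 = plant$v_in, i0 = 0, duty_fixed = NULL) {
  stopifnot(inherits(plant, "plant_params"), inherits(cfg, "pi_config"),
            inherits(load, "load_profile"))
  check_number(duration, "duration", lower = 0, closed_lower = FALSE)
  if (dt_sim > 1 / cfg$update_rate + 1e-12) {
    abort("`dt_sim` must not exceed one control period (1/update_rate).")
  }
  res <- boost_sim_core(
    plant$v_in, plant$inductance, plant$capacitance, plant$esr, plant$r_l,
    plant$duty_max, cfg$kp, cfg$ki, cfg$setpoint, cfg$integrator_limit,
    cfg$update_rate, dt_sim, load$breakpoints, load$resistances,
    duration, v0, i0,
    if (is.null(duty_fixed)) -1 else check_number(duty_fixed, "duty_fixed",
                                                  lower = 0,
                                                  upper = plant$duty_max)
  )
  out <- tibble::tibble(
    time_s = res$time_s, v_out = res$v_out, i_l = res$i_l,
    duty = res$duty, load_ohm = res$load_ohm
  )
  structure(out, plant = plant, cfg = cfg, load = load,
            v_final = res$v_final, i_final = res$i_final,
            class = c("boost_trace", class(out)))
}

#' Settling and regulation metrics of a boost transient
#'
#' * `settling_time_s`: last instant after `event_time` at which the output
#'   is outside the `setpoint +/- band` window, minus `event_time`; 0 if the
#'   output never leaves the band, `Inf` (with a warning) if it never
#'   re-enters.
#' * `steady_state_deviation`: mean `|v_out - setpoint| / setpoint` over the
#'   final 20 % of the trace.
#' * `overshoot`: `max(v_out - setpoint) / setpoint` after the event.
#'
#' @param trace A `boost_trace` from [simulate_boost()].
#' @param event_time Load-transition time, seconds (must lie inside the
#'   trace).
#' @param cfg The [pi_config()] used (for `setpoint` and `band`); defaults
#'   to the one stored in the trace.
#' @return A one-row tibble with the three metrics.
#' @export
settling_metrics <- function(trace, event_time, cfg = attr(trace, "cfg")) {
  if (event_time < min(trace$time_s) || event_time > max(trace$time_s)) {
    abort("`event_time` must lie inside the trace.")
  }
  sp <- cfg$setpoint
  post <- trace[trace$time_s >= event_time, ]
  dtc <- stats::median(diff(trace$time_s))
  outside <- abs(post$v_out - sp) > cfg$band
  settling <- if (!any(outside)) {
    0
  } else if (outside[length(outside)]) {
    warn("output never re-enters the settling band; settling time is Inf")
    Inf
  } else {
    max(post$time_s[outside]) + dtc - event_time
  }
  tail20 <- trace[trace$time_s >= max(trace$time_s) -
                    0.2 * diff(range(trace$time_s)), ]
  tibble::tibble(
    settling_time_s = settling,
    steady_state_deviation = mean(abs(tail20$v_out - sp)) / sp,
    overshoot = max(post$v_out - sp) / sp
  )
}
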