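---
title: "Modelling an EMG-triggered closed-loop TENS system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an EMG-triggered closed-loop TENS system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensloop)
```

`tensloop` is a digital twin of a wearable closed-loop TENS device: surface
EMG in, detected muscle-activation events, a regulated high-voltage supply,
and multi-channel biphasic stimulation out. This vignette is the package's
account of its models — what is physical, what is calibrated, and where the
genuinely open design choices were made.

## 1. Synthetic EMG

A recording is the sum of

* broadband Gaussian baseline noise with configurable RMS (mV at the
  electrode),
* optional power-line interference (a pure sinusoid, default 50 Hz),
* optional motion artifacts (low-pass-filtered random-walk transients
  below 10 Hz, default rate 0 — bench conditions), and
* one band-limited stochastic **carrier** per recording, multiplied by a
  per-burst envelope.

The carrier is white Gaussian noise passed through a zero-phase Butterworth
band-pass (two poles per sweep direction) over the 20–500 Hz surface-EMG
band and normalised to unit RMS, so `peak_amplitude` is exactly the plateau
RMS of a burst in electrode mV. Any band-limited stochastic carrier would be
admissible as a stand-in for real interference-pattern EMG; this one was
chosen because its spectrum is controllable and its amplitude scaling exact
(the test suite asserts ≥ 90 % of burst power inside the band, and exact
linearity). Envelopes are trapezoid (default, 10 % ramps) or Hann.
Annotations are the generator's own onsets/offsets — half-open
`[onset, offset)` intervals with `t = 0` at the first sample — never the
output of any detector.

What the generator does **not** model: motor-unit action-potential trains,
electrode–skin impedance, multi-muscle spatial structure. Detection results
on this corpus therefore measure the detector against *statistically*
EMG-like signals, not against physiological recordings.

The native synthesis rate is 4 kHz (8× the top band edge); the ADC model
later decimates to 1 kHz.

### The benchmark profiles

`generate_benchmark()` emulates a bench protocol of repeated
wrist-extension sessions: 20 bursts per session (~0.5 s long, ~2 s apart),
sessions split round-robin over virtual users, and a per-user amplitude
scale drawn once (log-normal, 15 % spread). Two profiles:

* **clean** — 1 mV plateau bursts over 0.05 mV baseline; linearly separable,
  used for the AUC = 1 anchor.
* **paper-bench** — the calibrated, partially masked regime: baseline RMS
  0.15 mV and per-burst envelope SNR drawn Normal(3 dB, 2 dB), truncated
  just above 0 dB, where SNR is defined as in-burst total RMS over baseline
  RMS (so the measured per-burst SNR reproduces the configured value). This
  profile is a **calibration stand-in** for recorded sessions that are not
  available — its burst counts, durations and SNR are declared choices, not
  derivations.

## 2. Acquisition front-end

The amplifier is algebraic: `out = G·v_diff + (G/10^(CMRR/20))·v_cm` with
G = 100 V/V and CMRR 80 dB by default. The Sallen–Key band-pass is realised
digitally as one 2nd-order Butterworth high-pass biquad at 20 Hz cascaded
with one low-pass biquad at 500 Hz (bilinear transform, prewarped corners);
the hardware gives topology and corners but not Q, and Butterworth
(Q = 0.707) is the standard maximally-flat reading. Filtering in the loop
path is **causal** — loop latency must include true group delay — and
zero-phase filtering exists only for offline analysis.

The ADC model applies a 6th-order Butterworth anti-alias low-pass at
0.45 × f_s, decimates by an integer factor to 1 kHz, and quantizes by
rounding to 12 bits over a bipolar ±vref/2 range behind a mid-supply
virtual ground (the single-supply front-end convention; midscale code
= 0 V). `codes_to_mv()` undoes the gain so detector thresholds are
electrode-referred — the 0.3 mV default threshold is stated in skin-signal
units, and the documented alternative (post-gain thresholds) is a pure
rescaling.

## 3. Event detection

The firmware chain is: causal moving average (default 5 samples = 5 ms at
1 kHz), causal sliding RMS (5 samples), fixed threshold with upward-crossing
detection (event time = first sample at/above threshold, as a sample-clocked
MCU would report), and a 0.5 s refractory that prevents re-triggering inside
one burst. Window lengths and refractory are not hardware-specified;
they are declared defaults, recorded in the configuration.

A consequence worth stating explicitly: the causal delay of the two-window
chain to a threshold crossing is close to `(w−1)/2` per stage — **4 ms** for
the 5 + 5 default at 1 kHz, measured in the package by comparing causal and
zero-phase (centered-window) crossing times. See Section 6 for how the latency
model accounts for this once.

The adaptive variant (`adaptive_threshold()`) tracks
`baseline mean + k·sd` over a trailing window that excludes samples at or
above the running threshold. Its value is drift immunity (the test suite
constructs a drifting baseline on which the fixed rule's detection time
shifts and its false-positive rate explodes, while the adaptive rule's do
not); on stationary noise it is only comparable to — not better than — a
well-placed fixed threshold.

## 4. Boost converter

The supply is modelled at the **averaged** (duty-cycle) level:

$$\frac{dI}{dt} = \frac{v_{in} - r_L I - (1-d)V}{L}, \qquad
  \frac{dV}{dt} = \frac{(1-d)I - v/R}{C},$$

with the measured output including the capacitor ESR drop. Switching ripple
is deliberately absent: the settling and regulation claims are
envelope-level, and PWM appears as the continuous duty `d`. Inductor current
is floored at zero (discontinuous-conduction guard), integration is
classical RK4 at 1 µs between 10 kHz controller updates, and a runaway
output (|v| > 10 × setpoint) aborts with a diagnostic. Halving the step
changes the cycle-averaged terminal voltage by < 0.1 % (asserted).

### The PI gains and their units — an open choice made explicit

The stock gains are Kp = 0.15 and Ki = 0.02, printed unitless as firmware
constants. Two readings exist:

1. *Continuous*: `integrator += error · dt`, Ki in duty/(V·s). Under this
   reading the integral term accumulates ~0.02 duty per volt-**second**: to
   hold the ≈ 0.95 duty that 80 V from 3.7 V requires, the integrator would
   need minutes — no choice of L and C can settle a load step into a
   ±2.5 V band within tens of milliseconds. (Numerically verified.)
2. *Discrete per-update*: `integrator += error` at each 10 kHz update, Ki in
   duty per volt-update — the form a sample-clocked MCU implements.

The package implements the discrete form, the only one under which the
printed gains achieve the measured behaviour. Error is expressed in volts at
the output (the divider is exact scaling, so this is a bookkeeping choice
that keeps the gains dimensionally usable). Anti-windup is conditional
integration: the integrator does not advance while the **clamped** duty is
saturated against the error sign. Freezing on the *unsaturated* candidate
instead deadlocks the integrator just below its equilibrium at light load —
a subtle but behaviour-changing distinction that the light-load regulation
test pins down.

### Plant constants

L, C and the parasitics are not device-documented. The defaults —
L = 100 µH with r_L = 0.1 Ω winding resistance, C = 100 µF, ESR 0.05 Ω,
duty_max = 0.97 — were chosen once so that a compact 100 V boost stage is
*well damped under the stock gains*: the winding resistance is the dominant
damping term of the averaged model, duty_max must exceed
1 − v_in/setpoint ≈ 0.954 for 80 V to be reachable at all, and the L/C pair
keeps the per-update current slew moderate (tens of µH would slew amperes
per control period under Kp = 0.15 duty/V and limit-cycle). With these
constants the simulated 10 kΩ → 500 Ω step at 80 V stays inside the ±2.5 V
band throughout (settling time 0 ms against the 20 ms bench bound) with
steady-state deviation well under 3 %.

The CCM voltage-ratio check `v/v_in = 1/(1−d)` runs **open loop**
(`duty_fixed`) on an ESR-free plant: under closed-loop control the small
control-rate limit cycle plus the nonlinearity of `1/(1−d)` make
mean-duty comparisons ill-posed.

## 5. Stimulation engine and channel isolation

Pulses are rectangular, charge-balanced biphasic pairs (leading phase sign
per polarity, optional interphase gap), rendered at 100 kHz so the shortest
100 µs phases carry ≥ 10 samples; charge balance is exact to one
sample-quantum by construction. The output stage is an **idealized current
source**: amplitude is met regardless of load, and deliverability is a
separate explicit check (`check_compliance()`), because 22 mA into a 10 kΩ
load implies 220 V — beyond a 100 V supply. Keeping the inconsistency
visible (instead of silently clipping) preserves the waveform and isolation
figures while flagging the compliance question.

Inter-channel leakage is modelled as instantaneous resistive crosstalk:
`observed_i = driven_i + Σ_j coupling[i,j]·driven_j`, with the default
matrix calibrated per victim channel from the packaged bench table
(`leakage_table()`, mean peaks at a 22 mA drive). A linear coupling matrix
is the *minimal* model consistent with peak-leakage measurements; it does
not model frequency-dependent or nonlinear coupling paths. The replicated
isolation study adds Normal(0, 0.02 mA) measurement noise to peak reads and
averages 10 repeats, mirroring the bench protocol.

## 6. Closed-loop latency

`run_trial()` pushes a synthetic recording through the full acquisition and
detection chain, then composes stage delays on top of the detection
instant:

* ADC sampling-phase alignment ~ Uniform(0, 1 ms),
* envelope-processing delay (see below),
* fixed firmware processing delay 1.4 ms,
* output-stage delay ~ Normal(5.5 ms, 0.6 ms), truncated at 0.

These constants are **calibrated to bench measurements of the hardware
loop, not derived**; their sum gives a 9.4 ms mean with ≈ 0.67 ms spread.
The latency study synthesizes a fresh single-burst recording per trial
(0.5 s burst, 2 mV plateau — a strong, function-generator-like test signal)
with per-trial derived seeds.

The envelope-delay term is accounted **once**, in one of two modes:
`"nominal"` (default) uses the calibrated 2.0 ms constant; `"measured"`
uses the empirical causal-vs-zero-phase crossing lag of the actual detector
configuration. For the default 5 + 5 windows that empirical lag is 4 ms, so
the two accountings agree only when the constant matches the chain — the
consistency test therefore runs them against a 3 + 3-window detector (chain
delay exactly 2 ms) and separately pins the 4 ms measurement. The nominal
constant is kept at 2.0 ms because the acceptance quantity is the
*hardware-calibrated* latency, and the stage decomposition is a stand-in.
A separate bench figure of ~12 ms exists for a different endpoint
(command-update delay); the detection-to-stimulation-onset definition used
here is the canonical one, and BLE transport (< 25 ms round trip) is
excluded from loop latency entirely.

`latency_stats()` reports mean, SD, a Shapiro–Wilk normality p-value and a
blocked one-way ANOVA p-value (k = 5 consecutive blocks) as a
trial-to-trial stability check, both delegated to the standard R routines.

## 7. Detection scoring and ROC

`score_detections()` matches detections to annotated onsets greedily by
absolute time difference within ±100 ms (the tolerance is a declared
default; the bench protocol does not state one). Specificity is defined
over decision windows tiling the inter-burst baseline (bursts padded by the
tolerance). Two methodological choices deserve emphasis:

* **Decision windows span 2 × tolerance.** The ±tolerance matching rule
  grants a true onset a 200 ms capture span; giving negative windows a
  100 ms span would make a detector firing at random score *above* the ROC
  diagonal (its asymptotic chance AUC works out to 2/3, which the package's
  own coin-flip test exposes). Equal spans put chance exactly on the
  diagonal, which is what an ROC requires.
* **The ROC sweep disables the refractory and floors the threshold sweep
  at the envelope's lower quartile.** The refractory is an actuation
  policy, not part of the decision statistic: with it enabled, low
  thresholds let baseline noise capture the refractory window and mask
  subsequent true onsets, so the low-threshold limb of the curve bends
  *away* from (1, 1). And below the envelope's bulk an upward-crossing
  trigger cannot re-arm (the signal rarely dips under the threshold),
  producing a second, degenerate family of operating points that
  interleaves with the proper curve when sorted by false-positive rate.
  Both pathologies are real behaviours of a crossing trigger — but they are
  not the detector's characterisable operating range, and a bench sweep
  would not include them.

AUC is the trapezoid rule over the swept operating points with endpoint
anchoring at (0, 0) and (1, 1); the optimal threshold maximises Youden's
J = sensitivity + specificity − 1. On the paper-bench profile the Youden
point trades a few sensitivity points for specificity relative to a
sensitivity-favoured reading of the same curve; the acceptance test checks
the operating point qualitatively and the AUC as a mean over three seeds.

## 8. Power and study-design statistics

Battery projections use `hours = capacity / (duty·I_active +
(1−duty)·I_idle)` — deliberately simple constant-current arithmetic (no
discharge-curve or temperature model). The paired sample-size calculation
uses the normal approximation `n = ceil(((z_{1−α[/2]} + z_{power})/d)²)`
with a **one-tailed** α: the target figure of 18 participants at d = 0.6,
α = 0.05, power 0.8 is reproduced only by the one-tailed normal
approximation (the iterative t-based calculation gives one to two more);
both choices are therefore documented rather than silently absorbed. RMSSD
and baseline normalization are exact closed forms, tested against
direct-summation oracles.

## 9. Problem sizes and numerical conventions

The shipped studies use: 10-session × 20-burst benchmarks at 4 kHz
(≈ 42 s/session), 100-trial latency studies, 200 ms converter runs at 1 µs
RK4 steps with 10 kHz control, and 100 kHz waveform rendering — sizes chosen
so a full verification pass runs in minutes on a laptop while keeping every
statistic comfortably inside its tolerance (CLT tolerance 0.25 ms on the
latency mean; ±0.03 seed-to-seed spread on AUC). All seeds are explicit;
identical configuration + seed is bit-reproducible. Degenerate inputs
(constant latency samples, zero baselines, empty truth, zero effective
current) are flagged or raised as typed conditions rather than returning
silent NaNs.

## 10. Known limitations

* Synthetic EMG is statistically, not physiologically, realistic; detector
  scores on it validate the *pipeline*, not clinical performance.
* The stage-delay model is a calibration; it cannot reveal latency effects
  absent from its functional form (e.g. load-dependent firmware jitter).
* The averaged converter model hides switching ripple, EMI and efficiency.
* The leakage model is linear and instantaneous.
* The human-study statistics implement design-stage contracts only; no
  trial data exist, and none are simulated.
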