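test_that("causal moving average matches its definition", {
  expect_equal(moving_average(rep(3.2, 50), 5), rep(3.2, 50))
  x <- rnorm(20)
  expect_equal(moving_average(x, 1), x)
  imp <- c(rep(0, 9), 1, rep(0, 10))
  expect_equal(moving_average(imp, 5)[10:14], rep(0.2, 5))
  expect_equal(moving_average(imp, 5)[15], 0)
  expect_error(moving_average(x, 0))
})

test_that("sliding RMS matches closed forms", {
  expect_equal(rms_envelope(rep(-2, 30), 5), rep(2, 30))
  expect_equal(rms_envelope(rep(0, 30), 5), rep(0, 30))
  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs
  env <- rms_envelope(3 * sin(2 * pi * 100 * t), 500)
  expect_lt(max(abs(env[500:2000] - 3 / sqrt(2))) / (3 / sqrt(2)), 0.01)
})

test_that("threshold crossings and refractory suppression behave as defined", {
  cfg <- detector_config(threshold = 0.3, refractory = 0.5)
  expect_equal(nrow(detect_events(rep(0.1, 1000), 1000, cfg)), 0)

  step <- c(rep(0, 99), rep(0.5, 200))
  ev <- detect_events(step, 1000, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_s, 99 / 1000)
  expect_equal(ev$env_mV, 0.5)

  # two crossings 0.1 s apart: refractory keeps one
  two <- rep(0, 1000)
  two[101:120] <- 0.5
  two[201:220] <- 0.5
  expect_equal(nrow(detect_events(two, 1000, cfg)), 1)
  cfg0 <- detector_config(threshold = 0.3, refractory = 0)
  expect_equal(nrow(detect_events(two, 1000, cfg0)), 2)
})

test_that("detection is causal: appending samples never changes past events", {
  set.seed(42)
  env <- abs(rnorm(2000, 0.2, 0.1))
  cfg <- detector_config(threshold = 0.45, refractory = 0.1)
  e1 <- detect_events(env, 1000, cfg)
  e2 <- detect_events(c(env, abs(rnorm(500, 0.2, 0.1))), 1000, cfg)
  expect_equal(head(e2, nrow(e1)), e1)
})

test_that("lowering the threshold never loses or postpones the first event", {
  set.seed(7)
  for (rep in 1:20) {
    env <- rms_envelope(rnorm(1500, 0, 0.2), 5)
    cfg_hi <- detector_config(threshold = 0.25, refractory = 0)
    cfg_lo <- detector_config(threshold = 0.12, refractory = 0)
    hi <- detect_events(env, 1000, cfg_hi)
    lo <- detect_events(env, 1000, cfg_lo)
    if (nrow(hi) > 0) {
      expect_gt(nrow(lo), 0)
      expect_lte(lo$t_s[1], hi$t_s[1])
    }
  }
})

test_that("the envelope chain commutes with amplitude scaling", {
  set.seed(3)
  x <- rnorm(1000)
  chain <- function(z) rms_envelope(moving_average(z, 5), 5)
  expect_equal(chain(2.7 * x), 2.7 * chain(x), tolerance = 1e-12)
})

test_that("adaptive threshold tracks a flat baseline exactly", {
  env <- rep(0.4, 500)
  thr <- adaptive_threshold(env, 1000, k_sigma = 3, baseline_window = 0.1)
  expect_equal(thr[5:500], rep(0.4, 496))
})

test_that("adaptive threshold is drift-immune where the fixed one is not", {
  fs <- 1000
  t <- (0:(8 * fs - 1)) / fs
  ramp <- pmin(pmax((t - 5) / 0.01, 0), 1)      # 10 ms rise at t = 5 s
  flat <- 0.2 + 0.8 * ramp
  drift <- 0.2 + 0.03 * t + 0.8 * ramp          # slow upward drift

  cross_fixed <- function(env) which(env >= 0.6)[1]
  shift_fixed <- abs(cross_fixed(drift) - cross_fixed(flat))
  expect_gte(shift_fixed, 1)

  cross_adaptive <- function(env) {
    thr <- adaptive_threshold(env, fs, k_sigma = 3, baseline_window = 2)
    which(env >= thr & t >= 4.9)[1]
  }
  expect_lt(abs(cross_adaptive(drift) - cross_adaptive(flat)), 1 + 1e-9)
})

test_that("adaptive thresholding controls false positives where fixed cannot", {
  set.seed(11)
  fs <- 1000
  env <- rms_envelope(rnorm(20000, 0, 0.1), 5)
  # stationary noise: both rules sit near mean + 3 sd and fire comparably
  thr_a <- adaptive_threshold(env, fs, k_sigma = 3, baseline_window = 2)
  fixed <- mean(env) + 3 * sd(env)
  expect_lt(abs(mean(env >= thr_a) - mean(env >= fixed)), 0.01)

  # drifting baseline: the fixed rule (set on the early segment) floods with
  # false positives while the adaptive rule tracks the drift
  drift <- env + seq(0, 0.2, length.out = length(env))
  thr_d <- adaptive_threshold(drift, fs, k_sigma = 3, baseline_window = 2)
  fixed_d <- mean(drift[1:2000]) + 3 * sd(drift[1:2000])
  fp_adaptive <- mean(drift >= thr_d)
  fp_fixed <- mean(drift >= fixed_d)
  expect_lt(fp_adaptive, 0.1 * fp_fixed)
})
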