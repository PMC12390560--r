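test_that("perfect and empty detections score as expected", {
  truth <- tibble::tibble(onset_s = c(1, 3, 5), offset_s = c(1.5, 3.5, 5.5))
  perfect <- tibble::tibble(t_s = truth$onset_s, env_mV = 1)
  sc <- score_detections(perfect, truth, duration = 7)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)

  none <- tibble::tibble(t_s = double(), env_mV = double())
  sc0 <- score_detections(none, truth, duration = 7)
  expect_equal(sc0$sensitivity, 0)
  expect_equal(sc0$specificity, 1)
  expect_equal(sc0$sensitivity + sc0$fn / (sc0$tp + sc0$fn), 1)

  empty_truth <- tibble::tibble(onset_s = double(), offset_s = double())
  expect_warning(scna <- score_detections(perfect, empty_truth, 7),
                 "undefined")
  expect_true(is.na(scna$sensitivity))
})

test_that("greedy matching agrees with the exhaustive matching oracle", {
  set.seed(31)
  for (case in 1:3) {
    n_on <- sample(2:5, 1)
    onsets <- sort(runif(n_on, 0, 10))
    det <- sort(c(onsets + rnorm(n_on, 0, 0.08), runif(3, 0, 10)))
    truth <- tibble::tibble(onset_s = onsets, offset_s = onsets + 0.3)
    sc <- score_detections(tibble::tibble(t_s = det, env_mV = 1), truth,
                           duration = 11)
    expect_equal(sc$tp, max_matching_oracle(det, onsets, 0.1))
    expect_equal(sc$fp, length(det) - sc$tp)
    expect_equal(sc$fn, n_on - sc$tp)
  }
})

test_that("the clean benchmark is perfectly separable (AUC 1)", {
  bench <- generate_benchmark(4, 2, "clean", seed = 3)
  roc <- roc_detection(bench)
  expect_equal(roc$auc, 1.0, tolerance = 1e-6)
  expect_equal(roc$sensitivity, 1)
  expect_equal(roc$specificity, 1)
})

test_that("a coin-flip detector scores chance-level AUC", {
  set.seed(17)
  truth <- tibble::tibble(onset_s = seq(1, 39, 2) + runif(20, -0.3, 0.3))
  truth$offset_s <- truth$onset_s + 0.5
  auc <- vapply(1:20, function(rep) {
    curve <- purrr::map_dfr(c(2, 5, 10, 20, 40, 80, 160), function(n_det) {
      det <- tibble::tibble(t_s = sort(runif(n_det, 0, 41)), env_mV = 1)
      score_detections(det, truth, duration = 41)
    })
    tensloop:::auc_trapezoid(1 - curve$specificity, curve$sensitivity)
  }, double(1))
  expect_lt(abs(mean(auc) - 0.5), 0.05)
})

test_that("detection scoring is invariant to monotone envelope rescaling", {
  set.seed(5)
  env <- rms_envelope(rnorm(3000, 0, 0.2), 5)
  cfg <- detector_config(threshold = 0.25, refractory = 0)
  a <- detect_events(env, 1000, cfg)
  cfg$threshold <- 0.25 * 3.7
  b <- detect_events(env * 3.7, 1000, cfg)
  expect_equal(a$t_s, b$t_s)
  expect_equal(b$env_mV, a$env_mV * 3.7)
})

test_that("battery projections reproduce the bench runtime arithmetic", {
  expect_equal(round(battery_runtime(power_model(active_current = 95)), 1),
               4.2)
  h <- battery_runtime(power_model(active_current = 45))
  expect_equal(round(h, 1), 8.9)
  expect_gt(h, 8)
  expect_error(battery_runtime(power_model(active_current = 10, duty = 0)),
               class = "tensloop_error_power")
  # homogeneity
  expect_equal(battery_runtime(power_model(battery_capacity = 800)),
               2 * battery_runtime(power_model(battery_capacity = 400)))
})

test_that("implied idle current solves the duty-cycle model", {
  expect_equal(implied_idle_current(95, 0.4, 45), (45 - 38) / 0.6)
  expect_equal(implied_idle_current(95, 0, 10), 10)
  expect_error(implied_idle_current(95, 1, 95))
  expect_error(implied_idle_current(95, 0.4, 10),
               class = "tensloop_error_power")
})

test_that("paired sample size matches the normal-approximation closed form", {
  expect_equal(sample_size_paired(study_design(0.6, 0.05, 0.8, "one")), 18L)
  expect_equal(sample_size_paired(study_design(0.6, 0.05, 0.8, "two")), 22L)
  expect_equal(sample_size_paired(study_design(10, 0.05, 0.8, "one")), 1L)

  # monotone over a grid: non-increasing in d and alpha, non-decreasing in
  # power
  for (a in c(0.01, 0.05)) for (p in c(0.8, 0.9)) {
    n_d <- vapply(c(0.3, 0.6, 0.9), function(d)
      sample_size_paired(study_design(d, a, p)), integer(1))
    expect_true(all(diff(n_d) <= 0))
  }
  n_a <- vapply(c(0.01, 0.05, 0.1), function(a)
    sample_size_paired(study_design(0.6, a, 0.8)), integer(1))
  expect_true(all(diff(n_a) <= 0))
  n_p <- vapply(c(0.7, 0.8, 0.9), function(p)
    sample_size_paired(study_design(0.6, 0.05, p)), integer(1))
  expect_true(all(diff(n_p) >= 0))
})

test_that("RMSSD matches closed forms and a direct-summation oracle", {
  expect_equal(rmssd(rep(800, 10)), 0)
  expect_equal(rmssd(c(800, 810, 800, 810)), 10)
  set.seed(2)
  rr <- 800 + cumsum(rnorm(50, 0, 15))
  acc <- 0
  for (i in 2:length(rr)) acc <- acc + (rr[i] - rr[i - 1])^2
  expect_equal(rmssd(rr), sqrt(acc / (length(rr) - 1)))
  expect_error(rmssd(800))
})

test_that("baseline normalization is exact and flags a zero baseline", {
  x <- c(rep(2, 100), rep(4, 100))
  out <- normalize_to_baseline(x, baseline_window = 1, fs = 100)
  expect_equal(out[1:100], rep(0, 100))
  expect_equal(out[101:200], rep(1, 100))

  set.seed(8)
  y <- runif(500, 1, 3)
  o <- normalize_to_baseline(y, 0.5, 100)
  m <- mean(y[1:50])
  expect_equal(o, (y - m) / m)
  expect_error(normalize_to_baseline(c(rep(0, 50), 1:50), 0.5, 100),
               class = "tensloop_error_baseline")
})
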