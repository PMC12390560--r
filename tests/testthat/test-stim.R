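test_that("biphasic pulse trains are charge balanced to one sample-quantum", {
  fs <- 1e5
  for (spec in list(pulse_spec(),
                    pulse_spec(amplitude = 22, phase_width = 2e-3,
                               frequency = 100),
                    pulse_spec(amplitude = 10, phase_width = 300e-6,
                               interphase_gap = 50e-6, frequency = 40,
                               polarity = "anodic-first"))) {
    x <- generate_biphasic(spec, fs, duration = 0.1)
    charge <- sum(x) / fs           # mA * s
    expect_lte(abs(charge), spec$amplitude / fs + 1e-12)
  }
})

test_that("per-phase charge of the 2 ms / 22 mA bench pulse is 44 uC", {
  fs <- 1e5
  spec <- pulse_spec(amplitude = 22, phase_width = 2e-3, frequency = 100)
  x <- generate_biphasic(spec, fs, duration = 0.01)
  q_pos <- sum(x[x > 0]) / fs / 1000     # A * s
  expect_equal(q_pos, 44e-6, tolerance = 1e-9)
})

test_that("degenerate pulse programs are rejected or zero", {
  expect_equal(max(abs(generate_biphasic(pulse_spec(amplitude = 0), 1e5,
                                         0.02))), 0)
  expect_error(pulse_spec(phase_width = 2.5e-3, interphase_gap = 6e-3,
                          frequency = 100), "period")
  expect_error(generate_biphasic(pulse_spec(phase_width = 100e-6), 5e4,
                                 0.01), "10 samples")
})

test_that("multi-channel rendering synchronizes and jitters reproducibly", {
  setup <- channel_setup(trigger_times = 1e-3, jitter_sd = 0)
  wf <- render_multichannel(setup, pulse_spec(), duration = 0.02, seed = 1)
  expect_equal(attr(wf, "onsets"), rep(1e-3, 6))
  mat <- tensloop:::waveform_matrix(wf)
  first_on <- apply(mat != 0, 2, which.max)
  expect_true(all(first_on == first_on[1]))
  expect_equal(unname(apply(abs(mat), 2, max)), rep(22, 6))

  jsetup <- channel_setup(trigger_times = 1e-3, jitter_sd = 1e-4)
  w1 <- render_multichannel(jsetup, pulse_spec(), duration = 0.02, seed = 9)
  w2 <- render_multichannel(jsetup, pulse_spec(), duration = 0.02, seed = 9)
  expect_identical(attr(w1, "onsets"), attr(w2, "onsets"))
  expect_gt(sd(attr(w1, "onsets")), 0)
})

test_that("crosstalk model reproduces the calibrated leakage ratios", {
  zero <- channel_setup(coupling = matrix(0, 6, 6))
  wf <- render_multichannel(zero, pulse_spec(), duration = 0.02, seed = 1,
                            channels = 1)
  expect_equal(tensloop:::waveform_matrix(apply_crosstalk(wf)),
               tensloop:::waveform_matrix(wf))

  cm <- matrix(0, 6, 6)
  cm[2, 1] <- 0.20 / 22
  setup <- channel_setup(coupling = cm)
  wf1 <- apply_crosstalk(render_multichannel(setup, pulse_spec(),
                                             duration = 0.02, seed = 1,
                                             channels = 1))
  iso <- measure_isolation(wf1, driven = 1)
  expect_equal(iso$peak_mA[2], 0.20, tolerance = 1e-9)

  # calibrated default matrix: worst-case leakage fraction below 1.2 %
  def <- channel_setup()
  wfd <- apply_crosstalk(render_multichannel(def, pulse_spec(),
                                             duration = 0.02, seed = 1,
                                             channels = 3))
  isod <- measure_isolation(wfd, driven = 3)
  expect_lte(max(isod$fraction[!isod$driven]), 0.012)
  expect_equal(max(isod$fraction[!isod$driven]), 0.20 / 22,
               tolerance = 1e-9)
})

test_that("replicated isolation study reproduces the bench table", {
  tab <- leakage_table()
  res <- isolation_study(seed = 5)
  expect_equal(res$channel, tab$channel)
  expect_true(all(abs(res$mean_mA - tab$mean_mA) <= 0.04))
  expect_true(all(res$sd_mA < 0.04))
})

test_that("leakage scales linearly with drive and is permutation-equivariant", {
  setup <- channel_setup()
  run <- function(amp, drv) {
    wf <- apply_crosstalk(render_multichannel(
      setup, pulse_spec(amplitude = amp), duration = 0.02, seed = 2,
      channels = drv
    ))
    measure_isolation(wf, driven = drv)$peak_mA
  }
  expect_equal(run(22, 1), 2 * run(11, 1), tolerance = 1e-12)

  perm <- c(3, 1, 2, 6, 4, 5)
  cmat <- default_coupling()
  psetup <- channel_setup(coupling = cmat[perm, perm])
  wfp <- apply_crosstalk(render_multichannel(psetup, pulse_spec(),
                                             duration = 0.02, seed = 2,
                                             channels = which(perm == 1)))
  base <- run(22, 1)
  permuted <- measure_isolation(wfp, driven = which(perm == 1))$peak_mA
  expect_equal(permuted, base[perm], tolerance = 1e-12)
})

test_that("compliance check applies Ohm's law against the supply", {
  out <- check_compliance(pulse_spec(amplitude = 22), load = 1e4,
                          v_supply = 100)
  expect_equal(out$required_voltage, 220)
  expect_false(out$compliant)
  boundary <- check_compliance(pulse_spec(amplitude = 10), load = 1e4,
                               v_supply = 100)
  expect_equal(boundary$required_voltage, 100)
  expect_true(boundary$compliant)
  expect_true(check_compliance(pulse_spec(amplitude = 0), 1e4)$compliant)
})
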