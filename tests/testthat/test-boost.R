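test_that("discrete PI step follows the per-update control law", {
  cfg <- pi_config(setpoint = 80)
  expect_equal(pi_step(0, 0, cfg)$duty, 0)

  st <- pi_step(1, 0, cfg)
  expect_equal(st$integrator, 1)
  expect_equal(st$duty, 0.15 * 1 + 0.02 * 1)

  # anti-windup: with the actuator pinned against a positive error the
  # integrator must not advance
  pinned <- pi_step(50, 5, cfg, duty_max = 0.97)
  expect_equal(pinned$duty, 0.97)
  expect_equal(pinned$integrator, 5)
})

test_that("compiled controller matches the reference pi_step exactly", {
  plant <- plant_params()
  cfg <- pi_config(setpoint = 60)
  tr <- simulate_boost(plant, cfg, load_profile(0, 5000), duration = 0.02,
                       dt_sim = 1e-6)
  s <- 0
  duty_replay <- vapply(seq_len(nrow(tr)), function(k) {
    st <- pi_step(cfg$setpoint - tr$v_out[k], s, cfg,
                  duty_max = plant$duty_max)
    s <<- st$integrator
    st$duty
  }, double(1))
  expect_equal(tr$duty, duty_replay, tolerance = 1e-12)
})

test_that("open-loop equilibrium obeys the CCM voltage ratio 1/(1-d)", {
  # ESR-free plant, small winding resistance for damping; 500 Ohm keeps the
  # inductor current well away from the zero floor
  plant <- plant_params(esr = 0, r_l = 0.05)
  cfg <- pi_config(setpoint = 60)
  for (d in c(0.7, 0.85, 0.9)) {
    tr <- simulate_boost(plant, cfg, load_profile(0, 500), duration = 0.3,
                         duty_fixed = d)
    ss <- tail(tr, 200)
    expect_gt(min(ss$i_l), 0)
    expect_equal(mean(ss$v_out) / plant$v_in, 1 / (1 - d), tolerance = 0.02)
  }
})

test_that("output regulates into the band and the error integrates away", {
  cfg <- pi_config(setpoint = 80)
  tr <- simulate_boost(plant_params(), cfg, load_profile(0, 1e4),
                       duration = 0.5)
  expect_lt(abs(tail(tr$v_out, 1) - 80), 0.5)
  expect_true(all(abs(tail(tr$v_out, 1000) - 80) <= 2.5))
})

test_that("with the controller disabled the output decays passively", {
  cfg <- pi_config(kp = 0, ki = 0, setpoint = 80)
  tr <- simulate_boost(plant_params(), cfg, load_profile(0, 1e4),
                       duration = 0.05, v0 = 50)
  expect_true(all(tr$duty == 0))
  expect_true(all(diff(tr$v_out) <= 1e-9))
})

test_that("settling metrics handle trivial and non-recovering traces", {
  cfg <- pi_config(setpoint = 80)
  flat <- tibble::tibble(time_s = seq(0, 0.2, 1e-4), v_out = 80,
                         i_l = 0.1, duty = 0.95, load_ohm = 1e4)
  m <- settling_metrics(flat, 0.05, cfg)
  expect_equal(m$settling_time_s, 0)
  expect_equal(m$steady_state_deviation, 0)
  expect_equal(m$overshoot, 0)

  off <- flat
  off$v_out <- 70
  expect_warning(m2 <- settling_metrics(off, 0.05, cfg), "never re-enters")
  expect_equal(m2$settling_time_s, Inf)
})

test_that("load-step transient meets the bench settling and regulation claims", {
  cfg <- pi_config(setpoint = 80)
  tr <- simulate_boost(plant_params(), cfg, load_step(1e4, 500, at = 0.05),
                       duration = 0.2)
  m <- settling_metrics(tr, 0.05, cfg)
  expect_lte(m$settling_time_s, 0.020)
  expect_lte(m$steady_state_deviation, 0.03)
})

test_that("halving the integration step leaves the solution unchanged", {
  cfg <- pi_config(setpoint = 80)
  a <- simulate_boost(plant_params(), cfg, load_profile(0, 2000),
                      duration = 0.1, dt_sim = 1e-6)
  b <- simulate_boost(plant_params(), cfg, load_profile(0, 2000),
                      duration = 0.1, dt_sim = 5e-7)
  # compare cycle-averaged terminal voltage: the small control-rate limit
  # cycle makes a pointwise comparison phase-sensitive
  va <- mean(tail(a$v_out, 200)); vb <- mean(tail(b$v_out, 200))
  expect_lt(abs(va - vb) / vb, 0.001)
})

test_that("delivered load energy never exceeds drawn source energy (lossless)", {
  plant <- plant_params(esr = 0, r_l = 0)
  cfg <- pi_config(setpoint = 60)
  tr <- simulate_boost(plant, cfg, load_profile(0, 5000), duration = 0.3)
  ss <- tr[tr$time_s >= 0.2, ]
  dt <- diff(ss$time_s)
  src <- sum(plant$v_in * head(ss$i_l, -1) * dt)
  load <- sum(head(ss$v_out, -1)^2 / head(ss$load_ohm, -1) * dt)
  expect_lte(load, src * 1.01)
})

test_that("runaway output aborts with a diagnostic", {
  cfg <- pi_config(setpoint = 50)
  expect_error(
    simulate_boost(plant_params(), cfg, load_profile(0, 1e4),
                   duration = 0.01, v0 = 600),
    "unstable"
  )
})
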