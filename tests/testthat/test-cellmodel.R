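test_that("the relaxed resting state is a fixed point of the stepper", {
  rest <- relaxed_rest_state()
  drift <- step_cell(rest, n_steps = 1000, dt = 0.02)
  expect_lt(abs(drift[["vm"]] - rest[["vm"]]), 0.01)
})

test_that("conductance multipliers scale their currents linearly and identity leaves them unchanged", {
  st <- as.numeric(control_steady()$state)
  # mid-action-potential state exercises every current
  st_ap <- step_cell(control_steady()$state, istim = 100, dt = 0.02,
                     n_steps = 50)
  st_ap <- step_cell(st_ap, n_steps = 2500)  # 50 ms into the AP
  for (s in list(st, as.numeric(st_ap))) {
    base <- infarctsim:::tt06_currents_cpp(s, 1, 1, 1)
    same <- infarctsim:::tt06_currents_cpp(s, 1, 1, 1)
    expect_identical(base, same)
    half <- infarctsim:::tt06_currents_cpp(s, 0.5, 0.25, 0.3)
    expect_equal(half[["INa"]], 0.5 * base[["INa"]])
    expect_equal(half[["IKr"]], 0.25 * base[["IKr"]])
    expect_equal(half[["IKs"]], 0.3 * base[["IKs"]])
    expect_equal(half[["IK1"]], base[["IK1"]])  # untouched current
  }
})

test_that("a threshold stimulus fires an action potential within 5 ms", {
  rest <- relaxed_rest_state()
  # 100 uA/cm^2 for 1 ms, then watch for the upstroke
  s <- step_cell(rest, istim = 100, dt = 0.02, n_steps = 50)
  fired <- s[["vm"]] > 0
  for (k in seq_len(4 * 50)) {
    if (fired) break
    s <- step_cell(s, dt = 0.02, n_steps = 1)
    fired <- s[["vm"]] > 0
  }
  expect_true(fired)
})

test_that("2 Hz pacing converges to a steady action potential duration", {
  ss <- control_steady()
  apd <- ss$apd_ms
  expect_gte(length(apd), 100)
  expect_lt(abs(apd[100] - apd[99]), 1)
  # plausible human endocardial APD90 at 2 Hz
  expect_gt(apd[100], 200)
  expect_lt(apd[100], 350)
})

test_that("pacing a single beat advances exactly one cycle", {
  run <- pace_cell(n_beats = 1, frequency = 2, sample_dt = 1)
  expect_equal(max(run$time_ms), 500)
  expect_equal(length(run$stim_onsets), 1)
})

test_that("steady APD increases as the delayed-rectifier conductances decrease", {
  scales <- list(c(1, 1), c(0.6, 0.65), c(0.20, 0.30))
  apd <- vapply(scales, function(sc) {
    p <- cell_params(gkr_scale = sc[1], gks_scale = sc[2])
    tail(pace_to_steady(p, n_beats = 60)$apd_ms, 1)
  }, numeric(1))
  expect_true(all(diff(apd) > 0))
})

test_that("prolonged-APD remodeling lengthens the steady APD beyond control", {
  ctrl <- tail(control_steady()$apd_ms, 1)
  prem <- apply_remodeling(cell_params(), remodeling_spec("prolonged_apd"))
  apd_p <- tail(pace_to_steady(prem, n_beats = 60)$apd_ms, 1)
  expect_gt(apd_p, ctrl)
})

test_that("maximal upstroke velocity falls monotonically with the INa scale", {
  vmax <- vapply(c(1.0, 0.5, 0.25), function(sc) {
    p <- cell_params(ina_scale = sc)
    st <- pace_to_steady(p, n_beats = 20)$state
    tr <- pace_cell(p, n_beats = 1, state0 = st, sample_dt = 0.1)
    max_upstroke_velocity(tr)
  }, numeric(1))
  expect_true(all(diff(vmax) < 0))
})

test_that("gating variables stay within [0, 1] across stimulation protocols", {
  gates <- c("m", "h", "j", "d", "f", "f2", "fcass", "r", "s",
             "xr1", "xr2", "xs", "rbar")
  s <- relaxed_rest_state()
  for (istim in c(0, 100, -50)) {
    s <- step_cell(s, istim = istim, dt = 0.02, n_steps = 200)
    expect_true(all(s[gates] >= 0 & s[gates] <= 1))
  }
  st <- control_steady()$state
  expect_true(all(st[gates] >= 0 & st[gates] <= 1))
})

test_that("a failed beat raises a no-capture error naming the beat", {
  expect_error(pace_to_steady(n_beats = 2, stim_amp = 1),
               "no-capture.*beat 1")
})

test_that("an invalid state names the first bad variable", {
  bad <- as.numeric(cell_initial_state())
  bad[15] <- NaN  # cai
  expect_error(step_cell(bad), "cai")
})

test_that("measure_apd recovers constructed pulse durations", {
  tm <- seq(0, 400, by = 0.5)
  vm <- ifelse(tm >= 10 & tm < 310, 40, -86)
  apd <- measure_apd(data.frame(time_ms = tm, vm_mV = vm), 0.9)
  expect_length(apd, 1)
  expect_equal(apd, 300, tolerance = 0.01)

  # two identical pulses give two equal APDs
  tm2 <- seq(0, 700, by = 0.5)
  vm2 <- ifelse((tm2 >= 10 & tm2 < 110) | (tm2 >= 400 & tm2 < 500), 40, -86)
  apd2 <- measure_apd(data.frame(time_ms = tm2, vm_mV = vm2), 0.9)
  expect_length(apd2, 2)
  expect_equal(apd2[1], apd2[2], tolerance = 1e-6)

  # no upstroke: empty result, not an error
  flat <- measure_apd(data.frame(time_ms = tm, vm_mV = rep(-86, length(tm))))
  expect_length(flat, 0)
})

test_that("the tissue repolarization level is the propagated AP's 90% level", {
  # a propagated action potential recorded away from the electrode puts
  # its 90%-repolarization level at the fixed -74 mV used by the tissue
  # event detector (single-cell traces overshoot: the stimulus inflates
  # the peak)
  sr <- planar_strip_run(0.143)
  vm <- sr$rec$vm[2, ]  # probe 3 cm from the electrode
  level <- min(vm) + 0.1 * (max(vm) - min(vm))
  expect_lt(abs(level - (-74)), 3)
})
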