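test_that("capture detection reads propagated activity at the probes", {
  g <- build_sheet(c(2, 20), 400)
  np <- (g$nx + 1) * (g$ny + 1)
  probe <- node_at(g, 1, 15)
  rec_silent <- structure(list(grid = g,
                               events = data.frame(node = integer(0),
                                                   time = numeric(0),
                                                   dir = integer(0))),
                          class = "vm_recording")
  expect_false(detect_capture(rec_silent, 0, probe))

  ev <- data.frame(node = seq_len(np),
                   time = 2 * rep(infarctsim:::node_coords(g)$y,
                                  each = g$nx + 1),
                   dir = 1L)
  rec_wave <- structure(list(grid = g, events = ev), class = "vm_recording")
  expect_true(detect_capture(rec_wave, 0, probe))
  # activity outside the window does not count
  expect_false(detect_capture(rec_wave, 200, probe))
})

test_that("the S1 train fails loudly when it cannot capture", {
  g <- strip_template(width_mm = 2, length_mm = 10)
  spec <- s1s2_spec(stim_amp = 1)  # far below threshold
  expect_error(run_s1s2(g, ci = 320, spec = spec, t_post = 100),
               "S1 no-capture")
})

test_that("an S2 at the basic cycle length is just a fourth S1", {
  tested <- capture_boundary()$tested
  expect_true(tested$captured[tested$ci == 500])
})

test_that("capture is monotone and the boundary is bracketed", {
  res <- capture_boundary()
  tested <- res$tested
  expect_false(is.na(res$min_ci))
  # every interval above the boundary captured, the next decrement failed
  expect_true(all(tested$captured[tested$ci > res$min_ci]))
  expect_equal(res$boundary_fail_ci, res$min_ci - 10)
})

test_that("the tissue capture boundary sits at the cell's transition to full responses", {
  # Space-clamped analogue of the S1-S2 protocol. Under the strong pacing
  # pulse the isolated cell has no all-or-none refractory boundary - its
  # premature response shortens gradually - so the comparison is made on
  # the response duration: at the tissue boundary the cell still mounts an
  # essentially full action potential (propagation requires one), while
  # 60 ms earlier the response has collapsed to a brief graded deflection.
  ss <- control_steady()$state
  s2_duration <- function(ci) {
    run <- infarctsim:::cell_run_cpp(as.numeric(ss), 1, 1, 1,
                                     c(0, 500, 1000, 1000 + ci), 1, 100,
                                     0.02, 0, 1000 + ci + 250, 0.5)
    win <- run$time_ms > 1000 + ci + 2
    sum(run$vm_mV[win] > -30) * 0.5
  }
  boundary <- capture_boundary()$min_ci
  expect_gt(s2_duration(boundary), 100)
  expect_lt(s2_duration(boundary - 60), 60)
})

test_that("capture calls are insensitive to the detection threshold and window", {
  sr <- planar_strip_run(0.143)
  # recompute probe activation times at shifted thresholds from the dense
  # probe traces: the upstroke is steep, so crossing times barely move
  tm <- sr$rec$times
  for (p in 1:2) {
    vm <- sr$rec$vm[p, ]
    t_at <- vapply(c(-40, -20, 0), function(th) {
      i <- which(vm[-length(vm)] < th & vm[-1] >= th)[1]
      tm[i] + (tm[i + 1] - tm[i]) * (th - vm[i]) / (vm[i + 1] - vm[i])
    }, numeric(1))
    expect_lt(diff(range(t_at)), 3)
  }
})
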