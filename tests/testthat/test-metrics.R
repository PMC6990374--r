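# synthetic recordings: field-map and classification logic is exercised on
# constructed event logs with known geometry-free answers

fake_rec <- function(grid, events, t_stop = 3000) {
  structure(list(grid = grid, events = events, t_stop = t_stop),
            class = "vm_recording")
}

# plane wave sweeping up a strip at 0.5 m/s (2 ms/mm), APD 300 ms
plane_wave_events <- function(grid, t0 = 0, apd = 300) {
  nc <- infarctsim:::node_coords(grid)
  np <- (grid$nx + 1) * (grid$ny + 1)
  y <- rep(nc$y, each = grid$nx + 1)
  at <- t0 + 2 * y
  data.frame(node = rep(seq_len(np), 2), time = c(at, at + apd),
             dir = rep(c(1L, -1L), each = np))
}

test_that("activation maps are linear for a constructed plane wave and mask silent nodes", {
  g <- build_sheet(c(2, 20), 400)
  ev <- plane_wave_events(g)
  silent <- node_index(g, 3, 10)
  ev <- ev[ev$node != silent, ]
  maps <- activation_repolarization_maps(fake_rec(g, ev), c(0, 500))
  # slope 2 ms/mm along y
  expect_equal(maps$at[1, 11] - maps$at[1, 1], 2 * 10 * 0.4, tolerance = 1e-9)
  expect_true(all(abs(maps$apd - 300) < 1e-9, na.rm = TRUE))
  expect_true(is.na(maps$at[3, 10]) && is.na(maps$rt[3, 10]) &&
                is.na(maps$apd[3, 10]))
})

test_that("conduction velocity follows from the activation-time difference", {
  g <- build_sheet(c(2, 20), 400)
  maps <- activation_repolarization_maps(fake_rec(g, plane_wave_events(g)),
                                         c(0, 500))
  p1 <- node_at(g, 1, 5)
  p2 <- node_at(g, 1, 15)
  expect_equal(conduction_velocity(maps, p1, p2), 0.5, tolerance = 1e-9)
  expect_error(conduction_velocity(maps, p2, p1), "non-causal")
})

test_that("RVI reduces to proximal repolarization minus distal activation", {
  g <- build_sheet(c(2, 20), 400)
  np <- (g$nx + 1) * (g$ny + 1)
  # uniform plane wave: RVI approximates APD (shifted by at most the
  # activation-time drop across the pairing radius)
  maps <- activation_repolarization_maps(fake_rec(g, plane_wave_events(g)),
                                         c(0, 500))
  rvi <- rvi_map(maps, pairing_radius_mm = 2)
  expect_true(all(rvi[!is.na(rvi)] <= 300 + 1e-9))
  expect_true(all(rvi[!is.na(rvi)] >= 300 - 2 * 2 * 2 - 1e-9))

  # two-site arithmetic: rt(proximal) - at(distal)
  mk <- function(at_d, rt_p) {
    p <- node_index(g, 2, 10)  # proximal
    d <- node_index(g, 2, 11)  # distal, 0.4 mm away
    ev <- data.frame(node = c(p, p, d), time = c(100, rt_p, at_d),
                     dir = c(1L, -1L, 1L))
    maps <- activation_repolarization_maps(fake_rec(g, ev), c(0, 1000))
    rvi_map(maps, pairing_radius_mm = 1)[d]
  }
  expect_equal(mk(400, 420), 20, tolerance = 1e-9)
  expect_equal(mk(430, 420), -10, tolerance = 1e-9)
})

test_that("RVI resembles the APD distribution during uncomplicated propagation", {
  sr <- planar_strip_run(0.143)
  maps <- activation_repolarization_maps(sr$rec, c(0, 450))
  # electrotonically uniform tissue: small spatial APD dispersion
  expect_lt(sd(maps$apd, na.rm = TRUE), 5)
  rvi <- rvi_map(maps, pairing_radius_mm = 2)
  expect_gt(min(rvi, na.rm = TRUE), 0)
  # RVI tracks APD point-by-point...
  ok <- !is.na(rvi) & !is.na(maps$apd)
  expect_lt(median(abs(rvi[ok] - maps$apd[ok])), 5)
  # ...and correlates with it away from the electrode band and sheet
  # edges, where boundary effects distort both maps
  inner <- matrix(FALSE, nrow(rvi), ncol(rvi))
  inner[11:(nrow(rvi) - 10), 11:(ncol(rvi) - 10)] <- TRUE
  oki <- ok & inner
  expect_gt(cor(rvi[oki], maps$apd[oki]), 0.9)
})

test_that("RVI-based block detection is insensitive to the pairing radius", {
  sr <- planar_strip_run(0.143)
  maps <- activation_repolarization_maps(sr$rec, c(0, 450))
  mins <- vapply(c(1, 2, 4), function(r) min(rvi_map(maps, r), na.rm = TRUE),
                 numeric(1))
  # all far above the 30%-of-APD block threshold, and mutually close
  expect_true(all(mins > 0.3 * 280))
  expect_lt(diff(range(mins)), 25)
})

# full synthetic S1-S2 recording on a coarse infarct geometry
synthetic_s1s2_rec <- function(kind = c("no_block", "block", "reentry"),
                               ci = 320) {
  kind <- match.arg(kind)
  g <- coarse_infarct()
  cfg <- sim_config()
  su <- infarctsim:::build_solver(g, conductivity_field(g), cfg)
  sites <- infarctsim:::protocol_sites(g)
  spec <- s1s2_spec()
  s1 <- (seq_len(spec$n_s1) - 1) * spec$bcl
  t_s2 <- s1[spec$n_s1] + ci
  nc <- infarctsim:::node_coords(g)
  np <- su$np
  y <- rep(nc$y, each = g$nx + 1)
  act <- which(su$active_mask)
  evs <- list()
  blocked_mask <- rep(FALSE, np)
  if (kind %in% c("block", "reentry")) {
    # S2 never enters the channel interior
    blocked_mask <- su$bz_mask & y > min(y[su$bz_mask]) + 1
  }
  for (t0 in c(s1, t_s2)) {
    nodes <- if (t0 == t_s2) act[!blocked_mask[act]] else act
    at <- t0 + 2 * y[nodes]
    evs[[length(evs) + 1]] <- data.frame(
      node = rep(nodes, 2), time = c(at, at + 290),
      dir = rep(c(1L, -1L), each = length(nodes)))
  }
  ev <- do.call(rbind, evs)
  if (kind == "block") {
    # one distal channel node re-excited late: proximal rt 80 ms before it
    d <- sites$channel_exit
    ev <- rbind(ev, data.frame(node = d, time = t_s2 + 350, dir = 1L))
  }
  if (kind == "reentry") {
    t_clear <- max(t_s2 + 2 * y[act][!blocked_mask[act]])
    cyc <- t_clear + 100 + (0:2) * 250
    ev <- rbind(ev,
                data.frame(node = rep(sites$dist_sentinel, 3), time = cyc,
                           dir = 1L))
  }
  rec <- fake_rec(g, ev[order(ev$time), ], t_stop = t_s2 + 1500)
  rec$setup <- su
  rec$protocol <- list(spec = spec, ci = ci, sites = sites, s1_onsets = s1,
                       t_s2 = t_s2, sigma_scale_bz = 1)
  rec
}

test_that("uniform propagation of every beat classifies as NO_BLOCK", {
  cls <- classify_outcome(synthetic_s1s2_rec("no_block"))
  expect_equal(cls$outcome, "NO_BLOCK")
  expect_equal(cls$n_cycles, 0L)
  expect_equal(cls$mean_apd, 290, tolerance = 1e-6)
})

test_that("a low-RVI region with failed S2 transit classifies as BLOCK", {
  cls <- classify_outcome(synthetic_s1s2_rec("block"))
  expect_equal(cls$outcome, "BLOCK_NO_REENTRY")
  expect_false(cls$s2_transit)
  expect_lt(cls$min_rvi, 0.3 * cls$mean_apd)
})

test_that("three sentinel re-activations classify as sustained re-entry with 3 cycles", {
  cls <- classify_outcome(synthetic_s1s2_rec("reentry"))
  expect_equal(cls$outcome, "REENTRY_SUSTAINED")
  expect_equal(cls$n_cycles, 3L)
})

test_that("an isthmus that never activates classifies as INEXCITABLE", {
  rec <- synthetic_s1s2_rec("no_block")
  bz <- which(rec$setup$bz_mask)
  rec$events <- rec$events[!(rec$events$node %in% bz), ]
  cls <- classify_outcome(rec)
  expect_equal(cls$outcome, "INEXCITABLE")
})

test_that("classification depends only on crossing events, not output sampling", {
  rec <- synthetic_s1s2_rec("reentry")
  rec$times <- seq(0, rec$t_stop)
  base <- classify_outcome(rec)
  rec2 <- rec
  rec2$times <- rec$times[seq(1, length(rec$times), by = 2)]
  cls2 <- classify_outcome(rec2)
  expect_identical(base$outcome, cls2$outcome)
  expect_identical(base$n_cycles, cls2$n_cycles)
})
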