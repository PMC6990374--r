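#' S1-S2 protocol specification
#'
#' Three S1 beats at a basic cycle length of 500 ms followed by one
#' premature S2 delivered at the same bottom-edge electrode, with the
#' coupling interval decremented in 10 ms steps from 500 ms when searching
#' for the capture boundary.
#'
#' @param n_s1 number of S1 beats.
#' @param bcl basic cycle length (ms).
#' @param ci_start initial (longest) S2 coupling interval (ms).
#' @param ci_step decrement of the coupling-interval search (ms).
#' @param ci_floor shortest coupling interval the search will try (ms).
#' @param stim_amp,stim_dur stimulus amplitude (uA/cm^2) and duration (ms).
#' @param capture_window time after a stimulus within which every probe
#'   must activate for the beat to count as captured (ms).
#' @return object of class `s1s2_spec`.
#' @export
s1s2_spec <- function(n_s1 = 3L, bcl = 500, ci_start = 500, ci_step = 10,
                      ci_floor = 150, stim_amp = 100, stim_dur = 1,
                      capture_window = 150) {
  stopifnot(n_s1 >= 1, bcl > 0, ci_step > 0, ci_start <= bcl,
            ci_floor > 0, ci_floor <= ci_start)
  structure(list(n_s1 = as.integer(n_s1), bcl = bcl, ci_start = ci_start,
                 ci_step = ci_step, ci_floor = ci_floor,
                 stim_amp = stim_amp, stim_dur = stim_dur,
                 capture_window = capture_window),
            class = "s1s2_spec")
}

# Named observation sites for a geometry. Infarct sheets get channel-anchored
# sites (sentinels 5 mm beyond either mouth, channel centre, mouths, sheet
# top); plain sheets get centreline capture probes along the propagation
# direction.
protocol_sites <- function(grid) {
  h <- grid$h_um / 1000
  W <- grid$nx * h
  L <- grid$ny * h
  if (!is.null(grid$scar)) {
    cx <- grid$scar_center[1]
    cy <- grid$scar_center[2]
    hl <- grid$scar$scar_half_length_mm
    w <- grid$scar$isthmus_width_mm
    # 1 mm-deep cross-section bands spanning the full channel width: a
    # through-going wavefront must activate some node of every band,
    # whatever the fibrotic texture, so band-ordered first-arrival times
    # resolve the direction of channel activation
    band <- function(y0, y1) {
      nc <- node_coords(grid)
      ix <- which(abs(nc$x - cx) < w / 2 - 1e-9)
      iy <- which(nc$y >= y0 - 1e-9 & nc$y <= y1 + 1e-9)
      as.vector(outer(ix, (iy - 1L) * (grid$nx + 1L), `+`))
    }
    list(
      prox_sentinel = node_at(grid, cx,
                              min(max(cy - hl - 5, 1.5), cy - hl - 0.4)),
      dist_sentinel = node_at(grid, cx, min(cy + hl + 5, L - 0.2)),
      channel_center = node_at(grid, cx, cy),
      channel_exit = node_at(grid, cx, cy + hl - 0.4),
      channel_entry = node_at(grid, cx, cy - hl + 0.4),
      entry_band = band(cy - hl, cy - hl + 1),
      centre_band = band(cy - 0.5, cy + 0.5),
      exit_band = band(cy + hl - 1, cy + hl),
      top_center = node_at(grid, cx, L - 1)
    )
  } else {
    list(
      mid = node_at(grid, W / 2, L / 2),
      threequarter = node_at(grid, W / 2, 0.75 * L),
      top_center = node_at(grid, W / 2, L - 1)
    )
  }
}

#' Did a stimulus capture the tissue?
#'
#' `TRUE` iff every probe node shows an upward crossing of the activation
#' threshold within `window` ms after `stim_time`. Probe nodes should sit
#' at least 5 mm from the stimulus electrode so that local stimulus
#' artefacts do not count as propagated activity.
#'
#' @param rec a `vm_recording`.
#' @param stim_time stimulus onset (ms).
#' @param probe probe node indices.
#' @param window capture window (ms).
#' @return logical.
#' @export
detect_capture <- function(rec, stim_time, probe, window = 150) {
  ev <- rec$events
  all(vapply(probe, function(p) {
    any(ev$node == p & ev$dir == 1 & ev$time > stim_time &
          ev$time <= stim_time + window)
  }, logical(1)))
}

#' Run the S1-S2 protocol on a tissue geometry
#'
#' Initializes every node from the 2 Hz / 100-beat steady state of its
#' region, delivers `n_s1` S1 beats at the bottom electrode followed by an
#' S2 at coupling interval `ci`, and simulates at least `t_post` ms beyond
#' S2 to observe re-entrant cycles. Raises an `S1 no-capture` error when
#' the S1 train fails to propagate.
#'
#' @param grid a `tissue_grid`.
#' @param ci S2 coupling interval (ms).
#' @param remodeling a [remodeling_spec()] for the border zone.
#' @param sigma_scale_bz conductivity scaling of the border zone.
#' @param spec an [s1s2_spec()].
#' @param config a [sim_config()].
#' @param t_post observation window after S2 (ms).
#' @param snap_dt optional snapshot interval (ms).
#' @param quiet_stop end early once the sheet is fully repolarized.
#' @param setup optional precomputed solver setup.
#' @param check_s1 verify S1 capture at the far probe (disable for
#'   deliberately inexcitable configurations).
#' @return a `vm_recording` with the protocol description attached
#'   (`$protocol`: sites, stimulus times, spec).
#' @export
run_s1s2 <- function(grid, ci = 320, remodeling = remodeling_spec("none"),
                     sigma_scale_bz = 1.0, spec = s1s2_spec(),
                     config = sim_config(), t_post = 1500, snap_dt = 0,
                     quiet_stop = TRUE, setup = NULL, check_s1 = TRUE) {
  stopifnot(ci > 0)
  cond <- conductivity_field(grid, sigma_scale_bz = sigma_scale_bz)
  if (is.null(setup)) setup <- build_solver(grid, cond, config, remodeling)
  sites <- protocol_sites(grid)
  s1_onsets <- (seq_len(spec$n_s1) - 1) * spec$bcl
  t_s2 <- s1_onsets[spec$n_s1] + ci
  rec <- run_monodomain(grid, cond, config, remodeling,
                        stim_onsets = c(s1_onsets, t_s2),
                        stim_dur = spec$stim_dur, stim_amp = spec$stim_amp,
                        t_end = t_s2 + t_post,
                        probe_nodes = unlist(sites, use.names = FALSE),
                        probe_dt = 1, snap_dt = snap_dt,
                        quiet_stop = quiet_stop, quiet_min_t = t_s2 + 100,
                        setup = setup)
  rec$protocol <- list(spec = spec, ci = ci, sites = sites,
                       s1_onsets = s1_onsets, t_s2 = t_s2,
                       sigma_scale_bz = sigma_scale_bz)
  if (check_s1) {
    far <- sites$top_center
    for (b in seq_along(s1_onsets)) {
      if (!detect_capture(rec, s1_onsets[b], far, spec$capture_window))
        stop(sprintf("S1 no-capture: beat %d did not reach the far probe", b))
    }
  }
  rec
}

#' Find the minimal capturing S2 coupling interval
#'
#' Decrements the coupling interval from `ci_start` in steps of `ci_step`
#' until S2 fails to capture, reusing the common S1-train prefix: the state
#' after the S1 train is advanced once, with intermediate states stored at
#' every candidate S2 time, so each candidate costs only the short
#' post-S2 window. Capture is judged at probes on the far half of the
#' geometry. Returns `NA` if even `ci_start` fails.
#'
#' @param grid a `tissue_grid` (typically a healthy strip).
#' @param spec an [s1s2_spec()].
#' @param remodeling,sigma_scale_bz border-zone remodeling (defaults: none).
#' @param config a [sim_config()].
#' @param post_window simulated time after S2 for capture detection (ms).
#' @return list with `min_ci` (smallest tested capturing interval, ms),
#'   `boundary_fail_ci`, and the `tested` data frame (ci, captured).
#' @export
find_min_capture_ci <- function(grid, spec = s1s2_spec(),
                                remodeling = remodeling_spec("none"),
                                sigma_scale_bz = 1.0,
                                config = sim_config(), post_window = NULL) {
  cond <- conductivity_field(grid, sigma_scale_bz = sigma_scale_bz)
  setup <- build_solver(grid, cond, config, remodeling)
  sites <- protocol_sites(grid)
  probes <- c(sites$mid, sites$threequarter, sites$top_center)
  probes <- probes[!vapply(probes, is.null, logical(1))]
  if (is.null(post_window)) post_window <- spec$capture_window + 30

  s1_onsets <- (seq_len(spec$n_s1) - 1) * spec$bcl
  t_base <- s1_onsets[spec$n_s1]  # last S1 onset; S2 at t_base + ci
  init <- region_initial_states(setup)

  # S1 train up to the last S1 onset
  if (t_base > 0) {
    seg <- run_monodomain(grid, cond, config, remodeling,
                          stim_onsets = s1_onsets[-spec$n_s1],
                          stim_dur = spec$stim_dur, stim_amp = spec$stim_amp,
                          t0 = 0, t_end = t_base, init = init,
                          probe_nodes = probes, setup = setup)
    for (b in seq_len(spec$n_s1 - 1)) {
      if (!detect_capture(seg, s1_onsets[b], probes, spec$capture_window))
        stop(sprintf("S1 no-capture: beat %d did not reach the probes", b))
    }
    init <- seg$final
  }

  # advance through the last S1, storing the state at every candidate S2 time
  cis <- seq(spec$ci_start, spec$ci_floor, by = -spec$ci_step)
  snap <- list()
  cur <- init
  t_cur <- t_base
  for (ci in sort(cis)) {
    t_snap <- t_base + ci
    seg <- run_monodomain(grid, cond, config, remodeling,
                          stim_onsets = if (t_cur == t_base) t_base else numeric(0),
                          stim_dur = spec$stim_dur, stim_amp = spec$stim_amp,
                          t0 = t_cur, t_end = t_snap, init = cur,
                          setup = setup)
    cur <- seg$final
    t_cur <- t_snap
    snap[[as.character(ci)]] <- cur
  }

  tested <- data.frame(ci = numeric(0), captured = logical(0))
  min_ci <- NA_real_
  fail_ci <- NA_real_
  for (ci in cis) {
    t_s2 <- t_base + ci
    rec <- run_monodomain(grid, cond, config, remodeling,
                          stim_onsets = t_s2, stim_dur = spec$stim_dur,
                          stim_amp = spec$stim_amp, t0 = t_s2,
                          t_end = t_s2 + post_window,
                          init = snap[[as.character(ci)]],
                          probe_nodes = probes, setup = setup)
    cap <- detect_capture(rec, t_s2, probes, spec$capture_window)
    tested <- rbind(tested, data.frame(ci = ci, captured = cap))
    if (cap) {
      min_ci <- ci
    } else {
      fail_ci <- ci
      break
    }
  }
  # monotone-capture sanity: every interval longer than the boundary captured
  if (nrow(tested) > 1 && any(!tested$captured[-nrow(tested)]))
    stop("capture was not monotone in the coupling interval")
  list(min_ci = min_ci, boundary_fail_ci = fail_ci, tested = tested)
}
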