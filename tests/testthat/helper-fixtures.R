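# Shared, lazily-built fixtures. Everything here is computed in code at
# test time; expensive artefacts are memoised for the duration of the
# test session so several test files can reuse one simulation.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# quiescent state relaxed for 10 s (the published initial conditions drift
# by a fraction of a mV; true rest is the relevant fixed point)
relaxed_rest_state <- function() {
  fixture("rest", function() step_cell(cell_initial_state(), n_steps = 500000))
}

control_steady <- function() {
  fixture("ss_control", function() pace_to_steady(n_beats = 100))
}

# planar-wave run on the 0.6 x 4 cm strip: full events to past
# repolarization, probes 1 cm and 3 cm from the electrode
planar_strip_run <- function(sigma = 0.143) {
  fixture(paste0("strip_", sigma), function() {
    g <- strip_template()
    cond <- conductivity_field(g, sigma_sm = sigma)
    p1 <- node_at(g, 3, 10)
    p2 <- node_at(g, 3, 30)
    rec <- run_monodomain(g, cond, sim_config(), t_end = 500,
                          probe_nodes = c(p1, p2), probe_dt = 0.5,
                          quiet_stop = TRUE, quiet_min_t = 100)
    list(rec = rec, grid = g, p1 = p1, p2 = p2)
  })
}

planar_cv <- function(sigma = 0.143) {
  sr <- planar_strip_run(sigma)
  maps <- activation_repolarization_maps(sr$rec, c(0, 200))
  conduction_velocity(maps, sr$p1, sr$p2)
}

# fine-grid (100 um, dt = 0.01 ms) planar CV: the continuum-limit
# reference used for the sqrt-conductivity law and mesh-refinement checks,
# where the 200 um grid under-resolves the sodium upstroke
fine_planar_cv <- function(sigma) {
  fixture(paste0("fine_", sigma), function() {
    g <- strip_template(width_mm = 2, length_mm = 24, h_um = 100)
    cond <- conductivity_field(g, sigma_sm = sigma)
    rec <- run_monodomain(g, cond, sim_config(dt = 0.01), t_end = 160,
                          quiet_stop = TRUE, quiet_min_t = 40)
    maps <- activation_repolarization_maps(rec, c(0, 160))
    conduction_velocity(maps, node_at(g, 1, 8), node_at(g, 1, 16))
  })
}

# capture-boundary search on the same healthy strip (reused by the
# protocol unit tests and the acceptance criterion)
capture_boundary <- function() {
  fixture("t3", function() find_min_capture_ci(strip_template()))
}

# a tiny infarct geometry at coarse spacing for fast protocol-level tests
coarse_infarct <- function() {
  fixture("coarse_infarct", function() small_infarct_template(h_um = 400))
}
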