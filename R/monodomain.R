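#' Default calibration of the conductivity-to-diffusivity conversion
#'
#' The monodomain diffusivity is `D = cal * sigma / (beta * cm)` (converted
#' to mm^2/ms). The dimensionless factor `cal` is fixed once so that the two
#' bulk conductivities the tissue model is specified by (0.143 and 0.064
#' S/m) propagate planar waves at their target velocities (0.6 and 0.4 m/s)
#' on the reference grid (200 um spacing, dt = 0.02 ms), balancing the
#' residual discretization error across the two targets.
#' @export
DIFFUSION_CAL <- 1.20

#' Simulation configuration
#'
#' @param dt time step (ms) shared by reaction and diffusion.
#' @param beta surface-to-volume ratio (1/um).
#' @param cm membrane capacitance per unit area (uF/cm^2).
#' @param diffusion_cal dimensionless calibration of the sigma-to-D
#'   conversion (see [DIFFUSION_CAL]).
#' @param up_threshold_mV upward crossing level defining activation (mV).
#' @param rep_level_mV downward crossing level defining repolarization (mV);
#'   -74 mV is the 90%-repolarization level of the TT06 endocardial action
#'   potential in tissue.
#' @param stim_depth_mm depth of the stimulated node band at the sheet's
#'   bottom edge (mm).
#' @param rev_every steps between refreshes of the cached reversal
#'   potentials.
#' @param max_cross per-node cap on recorded threshold crossings.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.02, beta = 0.14, cm = 1.0,
                       diffusion_cal = DIFFUSION_CAL,
                       up_threshold_mV = -20, rep_level_mV = -74,
                       stim_depth_mm = 1, rev_every = 25L,
                       max_cross = 64L) {
  stopifnot(dt > 0, dt <= 0.1, beta > 0, cm > 0, diffusion_cal > 0)
  structure(list(dt = dt, beta = beta, cm = cm,
                 diffusion_cal = diffusion_cal,
                 up_threshold_mV = up_threshold_mV,
                 rep_level_mV = rep_level_mV,
                 stim_depth_mm = stim_depth_mm,
                 rev_every = as.integer(rev_every),
                 max_cross = as.integer(max_cross),
                 ionic_model = "ten Tusscher-Panfilov 2006, endocardial"),
            class = "sim_config")
}

#' Per-element conductivity field
#'
#' Healthy tissue carries `sigma_sm`; border-zone elements carry
#' `sigma_sm * sigma_scale_bz` (gap-junction remodeling); scar and fibrotic
#' elements carry zero flux regardless.
#'
#' @param grid a `tissue_grid`.
#' @param sigma_sm bulk (isotropic) conductivity (S/m).
#' @param sigma_scale_bz dimensionless scaling of the border-zone
#'   conductivity.
#' @return object of class `conductivity_field` with the `nx x ny` `sigma`
#'   matrix (S/m).
#' @export
conductivity_field <- function(grid, sigma_sm = 0.143, sigma_scale_bz = 1.0) {
  stopifnot(inherits(grid, "tissue_grid"), sigma_sm >= 0, sigma_scale_bz >= 0)
  sig <- matrix(0, grid$nx, grid$ny)
  sig[grid$labels == TISSUE_LABELS[["HEALTHY"]]] <- sigma_sm
  sig[grid$labels == TISSUE_LABELS[["BZ"]]] <- sigma_sm * sigma_scale_bz
  structure(list(sigma = sig, sigma_sm = sigma_sm,
                 sigma_scale_bz = sigma_scale_bz),
            class = "conductivity_field")
}

# element diffusivities in mm^2/ms (sigma in S/m, beta in 1/um, cm in
# uF/cm^2; the 0.1 collects the unit conversions)
elem_diffusivity <- function(cond, config) {
  0.1 * config$diffusion_cal * cond$sigma / (config$beta * config$cm)
}

# Vertex-centred finite-volume coupling weights on the node grid. Each face
# between two nodes collects D/2 from each adjacent conducting element;
# missing (boundary) or non-conducting elements contribute nothing, which
# realises the homogeneous Neumann condition at the sheet edge and at
# scar/fibrosis interfaces. Weights are divided by the node control-volume
# fraction (1, 1/2, 1/4 at interior/edge/corner nodes).
build_solver <- function(grid, cond, config, remodeling = remodeling_spec("none")) {
  nx <- grid$nx; ny <- grid$ny
  h <- grid$h_um / 1000
  D <- elem_diffusivity(cond, config)
  stab <- h^2 / (4 * max(D))
  if (config$dt > stab + 1e-12)
    stop(sprintf("dt = %g ms violates the explicit stability bound %.4f ms",
                 config$dt, stab))
  np <- (nx + 1L) * (ny + 1L)
  Dpad <- matrix(0, nx + 2, ny + 2)
  Dpad[2:(nx + 1), 2:(ny + 1)] <- D

  # face conductivity sums
  Sx <- Dpad[2:(nx + 1), 1:(ny + 1)] + Dpad[2:(nx + 1), 2:(ny + 2)]  # nx x (ny+1)
  Sy <- Dpad[1:(nx + 1), 2:(ny + 1)] + Dpad[2:(nx + 2), 2:(ny + 1)]  # (nx+1) x ny

  fx <- rep(1, nx + 1); fx[c(1, nx + 1)] <- 0.5
  fy <- rep(1, ny + 1); fy[c(1, ny + 1)] <- 0.5
  fvol <- outer(fx, fy)
  denom <- 2 * h^2 * fvol

  wr <- matrix(0, nx + 1, ny + 1); wr[1:nx, ] <- Sx
  wl <- matrix(0, nx + 1, ny + 1); wl[2:(nx + 1), ] <- Sx
  wu <- matrix(0, nx + 1, ny + 1); wu[, 1:ny] <- Sy
  wd <- matrix(0, nx + 1, ny + 1); wd[, 2:(ny + 1)] <- Sy
  wr <- wr / denom; wl <- wl / denom; wu <- wu / denom; wd <- wd / denom

  nb_idx <- matrix(-1L, 4, np)
  nb_w <- matrix(0, 4, np)
  lin <- matrix(seq_len(np) - 1L, nx + 1, ny + 1)  # 0-based
  put <- function(slot, w, di, dj) {
    src <- which(w > 0, arr.ind = TRUE)
    if (nrow(src) == 0) return()
    tgt <- cbind(src[, 1] + di, src[, 2] + dj)
    n0 <- lin[src] + 1L
    nb_idx[slot, n0] <<- lin[tgt]
    nb_w[slot, n0] <<- w[src]
  }
  put(1L, wl, -1L, 0L)
  put(2L, wr, +1L, 0L)
  put(3L, wd, 0L, -1L)
  put(4L, wu, 0L, +1L)

  # active nodes: touch at least one conducting element
  Cpad <- matrix(FALSE, nx + 2, ny + 2)
  Cpad[2:(nx + 1), 2:(ny + 1)] <- D > 0
  touch <- function(M) {
    M[1:(nx + 1), 1:(ny + 1)] | M[2:(nx + 2), 1:(ny + 1)] |
      M[1:(nx + 1), 2:(ny + 2)] | M[2:(nx + 2), 2:(ny + 2)]
  }
  active <- touch(Cpad)

  # remodeled nodes: touch at least one (conducting) border-zone element
  Bpad <- matrix(FALSE, nx + 2, ny + 2)
  Bpad[2:(nx + 1), 2:(ny + 1)] <- grid$labels == TISSUE_LABELS[["BZ"]]
  bznode <- touch(Bpad) & active

  gna <- rep(1, np); gkr <- rep(1, np); gks <- rep(1, np)
  gna[bznode] <- remodeling$ina_scale
  gkr[bznode] <- remodeling$gkr_scale
  gks[bznode] <- remodeling$gks_scale

  nc <- node_coords(grid)
  list(grid = grid, cond = cond, config = config, remodeling = remodeling,
       np = np, h = h, active = which(active) - 1L,
       active_mask = as.vector(active), bz_mask = as.vector(bznode),
       nb_idx = nb_idx, nb_w = nb_w, gna = gna, gkr = gkr, gks = gks,
       node_x = rep(nc$x, times = ny + 1), node_y = rep(nc$y, each = nx + 1),
       fvol = as.vector(fvol), stability_dt = stab)
}

#' Assemble the diffusion operator as a sparse matrix
#'
#' Returns the linear operator `L` (1/ms) over node voltages such that
#' `dV/dt = L V` describes pure diffusion: a flux-conservative 5-point
#' stencil with zero flux across scar/fibrotic faces and the sheet edge.
#' Rows sum to zero; `diag(vol) %*% L` is symmetric (discrete charge
#' conservation).
#'
#' @param grid a `tissue_grid`.
#' @param cond a [conductivity_field()].
#' @param config a [sim_config()]; supplies `beta`, `cm` and the
#'   calibration factor.
#' @return a sparse `Matrix::dgCMatrix` of dimension n_nodes x n_nodes.
#' @export
assemble_diffusion <- function(grid, cond, config = sim_config()) {
  su <- build_solver(grid, cond, config)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (q in 1:4) {
    sel <- which(su$nb_idx[q, ] >= 0 & su$nb_w[q, ] > 0)
    ii <- c(ii, sel, sel)
    jj <- c(jj, su$nb_idx[q, sel] + 1L, sel)
    xx <- c(xx, su$nb_w[q, sel], -su$nb_w[q, sel])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(su$np, su$np))
}

#' Nearest node to sheet coordinates
#'
#' @param grid a `tissue_grid`.
#' @param x_mm,y_mm coordinates (mm).
#' @return 1-based linear node index.
#' @export
node_at <- function(grid, x_mm, y_mm) {
  h <- grid$h_um / 1000
  i <- pmin(pmax(round(x_mm / h) + 1L, 1L), grid$nx + 1L)
  j <- pmin(pmax(round(y_mm / h) + 1L, 1L), grid$ny + 1L)
  node_index(grid, as.integer(i), as.integer(j))
}

# stimulated node band at the bottom edge (active nodes with y <= depth)
bottom_stim_nodes <- function(setup) {
  depth <- setup$config$stim_depth_mm
  which(setup$active_mask & setup$node_y <= depth + 1e-9)
}

# initial per-node states from region steady states (2 Hz x 100 beats)
region_initial_states <- function(setup, n_beats = 100L) {
  ctrl <- steady_state_cached(cell_params(), 2.0, n_beats, setup$config$dt)$state
  np <- setup$np
  V <- rep(ctrl[1], np)
  S18 <- matrix(ctrl[-1], 18, np)
  if (any(setup$bz_mask)) {
    rm <- setup$remodeling
    bzp <- cell_params(ina_scale = rm$ina_scale, gkr_scale = rm$gkr_scale,
                       gks_scale = rm$gks_scale)
    bzs <- steady_state_cached(bzp, 2.0, n_beats, setup$config$dt)$state
    V[setup$bz_mask] <- bzs[1]
    S18[, setup$bz_mask] <- bzs[-1]
  }
  list(V = V, S18 = S18)
}

#' Run the monodomain model
#'
#' Operator-unsplit explicit advance: at every step of `dt` the TT06
#' reaction term and the finite-difference diffusion term are applied
#' together. Tissue is initialized from the 2 Hz / 100-beat single-cell
#' steady state of each region (control for healthy tissue, remodeled for
#' the border zone). Records probe-node voltages, threshold-crossing events
#' (activation at `up_threshold_mV`, repolarization at `rep_level_mV`, both
#' sub-dt interpolated), optional full-field snapshots, and the final state.
#'
#' @param grid a `tissue_grid`.
#' @param cond a [conductivity_field()]; default: uniform 0.143 S/m.
#' @param config a [sim_config()].
#' @param remodeling a [remodeling_spec()] applied to border-zone nodes.
#' @param stim_onsets stimulus onset times (ms).
#' @param stim_dur,stim_amp stimulus duration (ms) and amplitude (uA/cm^2).
#' @param t0,t_end simulation window (ms).
#' @param stim_nodes stimulated node indices; default: bottom edge band.
#' @param init optional `list(V, S18)` initial state (for segment chaining).
#' @param probe_nodes node indices whose voltage is recorded densely.
#' @param probe_dt probe sampling interval (ms).
#' @param snap_dt full-field snapshot interval (ms), 0 = off.
#' @param stop_nodes early-exit node set: the run ends `stop_delay` ms after
#'   any of these nodes activates.
#' @param stop_delay see `stop_nodes`.
#' @param quiet_stop end the run early once the whole sheet is repolarized
#'   (max Vm < -75 mV) and no stimulus is pending.
#' @param quiet_min_t earliest time (ms) the quiescence exit may trigger.
#' @param setup optional precomputed solver setup (from repeated runs on
#'   the same geometry).
#' @return object of class `vm_recording`.
#' @export
run_monodomain <- function(grid, cond = NULL, config = sim_config(),
                           remodeling = remodeling_spec("none"),
                           stim_onsets = 0, stim_dur = 1, stim_amp = 100,
                           t0 = 0, t_end = 500, stim_nodes = NULL,
                           init = NULL, probe_nodes = integer(0),
                           probe_dt = 1, snap_dt = 0,
                           stop_nodes = integer(0), stop_delay = 0,
                           quiet_stop = FALSE, quiet_min_t = 0,
                           setup = NULL) {
  if (is.null(setup)) {
    if (is.null(cond)) cond <- conductivity_field(grid)
    setup <- build_solver(grid, cond, config, remodeling)
  }
  config <- setup$config
  if (is.null(stim_nodes)) stim_nodes <- bottom_stim_nodes(setup)
  if (is.null(init)) init <- region_initial_states(setup)

  res <- mono_run_cpp(init$V, init$S18, setup$active,
                      setup$nb_idx, setup$nb_w,
                      setup$gna, setup$gkr, setup$gks,
                      as.integer(stim_nodes) - 1L, stim_onsets, stim_dur,
                      stim_amp, config$dt, t0, t_end,
                      as.integer(probe_nodes) - 1L, probe_dt,
                      config$up_threshold_mV, config$rep_level_mV,
                      config$max_cross, snap_dt,
                      as.integer(stop_nodes) - 1L, stop_delay,
                      quiet_stop, -75, quiet_min_t,
                      config$rev_every, TRUE, TRUE)
  if (identical(res$reason, "unstable"))
    stop(sprintf("numerical instability at t = %.3f ms, node %d",
                 res$bad_t, res$bad_node))
  structure(list(
    grid = setup$grid, config = config, remodeling = setup$remodeling,
    setup = setup,
    times = res$probe_t,
    vm = res$probe_v,
    probe_nodes = probe_nodes,
    events = data.frame(node = res$cross_node, time = res$cross_time,
                        dir = res$cross_dir),
    up_count = res$up_count, down_count = res$down_count,
    final = list(V = res$V, S18 = res$S18),
    t0 = t0, t_stop = res$t_stop, reason = res$reason,
    snap_t = res$snap_t, snapshots = res$snapshots,
    stim = list(nodes = stim_nodes, onsets = stim_onsets, dur = stim_dur,
                amp = stim_amp)),
    class = "vm_recording")
}

#' @export
print.vm_recording <- function(x, ...) {
  cat(sprintf("vm_recording: %d nodes, t = [%g, %g] ms (%s), %d crossings\n",
              x$setup$np, x$t0, x$t_stop, x$reason, nrow(x$events)))
  invisible(x)
}
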