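#' Single-beat isthmus traversal test
#'
#' Delivers one S1 at the bottom edge of a traversal geometry (full-width
#' scar belt, see [traversal_template()]) and reports whether any node
#' above the scar belt activates within `t_max` ms. Because the belt spans
#' the full sheet width, the fibrotic channel is the only conducting path,
#' so activation above the belt is equivalent to wavefront traversal of
#' the isthmus. The run exits as soon as traversal is detected or the
#' wavefront dies out.
#'
#' @param grid a traversal geometry, optionally with fibrosis.
#' @param config a [sim_config()].
#' @param t_max observation window (ms).
#' @param remodeling border-zone remodeling (default none).
#' @param sigma_scale_bz border-zone conductivity scaling.
#' @return list with `traversed` (logical), `t_exit` (first activation
#'   above the belt, ms, or `NA`), and `t_stop`.
#' @export
isthmus_traversal <- function(grid, config = sim_config(), t_max = 400,
                              remodeling = remodeling_spec("none"),
                              sigma_scale_bz = 1.0) {
  stopifnot(!is.null(grid$scar))
  cond <- conductivity_field(grid, sigma_scale_bz = sigma_scale_bz)
  setup <- build_solver(grid, cond, config, remodeling)
  cy <- grid$scar_center[2]
  hl <- grid$scar$scar_half_length_mm
  above <- which(setup$active_mask & setup$node_y > cy + hl + 0.5)
  if (length(above) == 0) stop("no active nodes above the scar belt")
  rec <- run_monodomain(grid, cond, config, remodeling,
                        stim_onsets = 0, t_end = t_max,
                        stop_nodes = above, stop_delay = 0,
                        quiet_stop = TRUE, quiet_min_t = 20,
                        setup = setup)
  ev <- rec$events
  hits <- ev$time[ev$dir == 1 & ev$node %in% above]
  list(traversed = length(hits) > 0,
       t_exit = if (length(hits) > 0) min(hits) else NA_real_,
       t_stop = rec$t_stop)
}

#' Maximum fibrosis density that still lets the S1 beat through
#'
#' For each density, builds `n_seeds` seeded fibrosis patterns in the
#' traversal geometry and runs [isthmus_traversal()]; returns the largest
#' density at which at least one pattern lets the wavefront through, and
#' the per-density traversal counts.
#'
#' @param densities fibrosis densities to scan.
#' @param n_seeds seeded topologies per density.
#' @param root_seed root seed from which pattern seeds derive (see
#'   [run_sweep()] for the scheme).
#' @param template a traversal geometry (default [traversal_template()]).
#' @param config a [sim_config()].
#' @param t_max observation window per run (ms).
#' @return list with `max_density` (largest traversing density, or `NA`),
#'   and `counts` (data frame: density, n_traversed, n_seeds).
#' @export
max_traversing_density <- function(densities = c(0.50, 0.55), n_seeds = 10L,
                                   root_seed = 1L,
                                   template = traversal_template(),
                                   config = sim_config(), t_max = 400) {
  counts <- data.frame(density = densities, n_traversed = 0L,
                       n_seeds = as.integer(n_seeds))
  for (di in seq_along(densities)) {
    d <- densities[di]
    for (r in seq_len(n_seeds)) {
      g <- generate_fibrosis(template, d, fibrosis_seed(root_seed, d, r))
      tr <- isthmus_traversal(g, config, t_max)
      if (tr$traversed)
        counts$n_traversed[di] <- counts$n_traversed[di] + 1L
    }
  }
  ok <- counts$density[counts$n_traversed > 0]
  list(max_density = if (length(ok) > 0) max(ok) else NA_real_,
       counts = counts)
}
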