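#' Vulnerability sweep specification
#'
#' The default is a reduced grid (scaling factors {0.1, 0.25, 0.5, 1.0},
#' fibrosis {0, 0.25, 0.5}, 3 topologies per density) sized for desk-scale
#' runs; `full_grid = TRUE` switches to the 0.05-step axes (0.10-1.00 for
#' the INa and conductivity scalings, 0-0.90 for fibrosis, 10 topologies).
#'
#' @param ina_scales INa scaling factors of the border zone.
#' @param sigma_scales conductivity scaling factors of the border zone.
#' @param fib_densities fibrosis densities.
#' @param n_seeds fibrosis topologies per density.
#' @param mode remodeling mode of the functional arm: `"reduced_ina"` or
#'   `"prolonged_apd"` (comparison arm; `ina_scales` is ignored and the
#'   single prolonged-APD cell is used).
#' @param ci S2 coupling interval (ms).
#' @param full_grid use the full 0.05-step axes.
#' @return object of class `sweep_spec`.
#' @export
sweep_spec <- function(ina_scales = c(0.1, 0.25, 0.5, 1.0),
                       sigma_scales = c(0.1, 0.25, 0.5, 1.0),
                       fib_densities = c(0, 0.25, 0.5),
                       n_seeds = 3L,
                       mode = c("reduced_ina", "prolonged_apd"),
                       ci = 320, full_grid = FALSE) {
  mode <- match.arg(mode)
  if (full_grid) {
    ina_scales <- seq(0.10, 1.00, by = 0.05)
    sigma_scales <- seq(0.10, 1.00, by = 0.05)
    fib_densities <- seq(0, 0.90, by = 0.05)
    n_seeds <- 10L
  }
  stopifnot(length(ina_scales) > 0, length(sigma_scales) > 0,
            length(fib_densities) > 0, n_seeds >= 1)
  structure(list(ina_scales = ina_scales, sigma_scales = sigma_scales,
                 fib_densities = fib_densities, n_seeds = as.integer(n_seeds),
                 mode = mode, ci = ci),
            class = "sweep_spec")
}

# deterministic per-row fibrosis seed: reproducible in isolation from the
# root seed, the density (in percent) and the topology replicate
fibrosis_seed <- function(root_seed, density, replicate) {
  as.integer((root_seed * 1000 + round(density * 100) * 10 + replicate) %%
               .Machine$integer.max)
}

#' Run a vulnerability parameter sweep
#'
#' One S1-S2 run per combination of (INa scale, conductivity scale,
#' fibrosis density, topology seed), each classified with
#' [classify_outcome()]. Individual run failures are recorded as
#' `"ERROR"` rows without aborting the sweep. When `cache_dir` is given,
#' every row is cached on disk keyed by the full parameter tuple, making
#' the sweep resumable.
#'
#' @param spec a [sweep_spec()].
#' @param template a `tissue_grid` with scar/isthmus labels (fibrosis is
#'   added per row), or a function returning one.
#' @param config a [sim_config()].
#' @param root_seed root seed from which per-row fibrosis seeds derive.
#' @param t_post observation window after S2 (ms).
#' @param cache_dir optional directory for per-row result caching.
#' @param verbose print one line per run.
#' @return a `data.frame` of class `vulnerability_table` with one row per
#'   run: parameters, `outcome`, `n_cycles`, `mean_apd`, `min_rvi`.
#' @export
run_sweep <- function(spec = sweep_spec(), template = small_infarct_template(),
                      config = sim_config(), root_seed = 1L, t_post = 1200,
                      cache_dir = NULL, verbose = FALSE) {
  if (is.function(template)) template <- template()
  stopifnot(inherits(template, "tissue_grid"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)

  ina_axis <- if (spec$mode == "prolonged_apd") 1.0 else spec$ina_scales
  combos <- expand.grid(ina_scale = ina_axis,
                        sigma_scale = spec$sigma_scales,
                        fib_density = spec$fib_densities,
                        replicate = seq_len(spec$n_seeds),
                        KEEP.OUT.ATTRS = FALSE)
  # fibrosis-free rows need no topology replicates
  combos <- combos[combos$fib_density > 0 | combos$replicate == 1, ]

  rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    cb <- combos[k, ]
    seed <- fibrosis_seed(root_seed, cb$fib_density, cb$replicate)
    key <- sprintf("row_%s_%s_%s_%d_%d.rds", cb$ina_scale, cb$sigma_scale,
                   cb$fib_density, cb$replicate, seed)
    if (!is.null(cache_dir) && file.exists(file.path(cache_dir, key))) {
      rows[[k]] <- readRDS(file.path(cache_dir, key))
      next
    }
    res <- tryCatch({
      grid <- template
      if (cb$fib_density > 0)
        grid <- generate_fibrosis(grid, cb$fib_density, seed)
      rem <- if (spec$mode == "prolonged_apd") remodeling_spec("prolonged_apd")
             else remodeling_spec("reduced_ina", cb$ina_scale)
      rec <- run_s1s2(grid, ci = spec$ci, remodeling = rem,
                      sigma_scale_bz = cb$sigma_scale, config = config,
                      t_post = t_post, check_s1 = FALSE)
      cls <- classify_outcome(rec)
      data.frame(ina_scale = cb$ina_scale, sigma_scale = cb$sigma_scale,
                 fib_density = cb$fib_density, replicate = cb$replicate,
                 seed = seed, outcome = cls$outcome, n_cycles = cls$n_cycles,
                 mean_apd = cls$mean_apd, min_rvi = cls$min_rvi,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(ina_scale = cb$ina_scale, sigma_scale = cb$sigma_scale,
                 fib_density = cb$fib_density, replicate = cb$replicate,
                 seed = seed, outcome = "ERROR", n_cycles = NA_integer_,
                 mean_apd = NA_real_, min_rvi = NA_real_,
                 stringsAsFactors = FALSE)
    })
    if (!is.null(cache_dir)) saveRDS(res, file.path(cache_dir, key))
    if (verbose)
      message(sprintf("ina=%.2f sigma=%.2f fib=%.2f rep=%d -> %s",
                      cb$ina_scale, cb$sigma_scale, cb$fib_density,
                      cb$replicate, res$outcome))
    rows[[k]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vulnerability_table", "data.frame")
  attr(out, "spec") <- spec
  attr(out, "root_seed") <- root_seed
  out
}

#' Block / re-entry probabilities from a vulnerability table
#'
#' `P_block = n_block / N` and `P_reentry = n_reentry / N` per group, with
#' inexcitable runs removed from both numerator and denominator; groups
#' whose runs are all inexcitable are masked (`NA`). Re-entrant outcomes
#' count as blocked (the re-entry arises from the blocked beat).
#'
#' @param table a `vulnerability_table`.
#' @param group_axes column names to aggregate over (at most two).
#' @return data frame with the group axes, `N` (after exclusion),
#'   `n_excluded`, `p_block`, `p_reentry`, `p_sustained`.
#' @export
compute_pb <- function(table, group_axes = c("ina_scale", "sigma_scale")) {
  stopifnot(nrow(table) > 0, length(group_axes) >= 1, length(group_axes) <= 2,
            all(group_axes %in% names(table)))
  sp <- split(seq_len(nrow(table)),
              lapply(group_axes, function(a) table[[a]]), drop = FALSE)
  rows <- lapply(sp, function(idx) {
    if (length(idx) == 0) return(NULL)
    sub <- table[idx, ]
    keep <- !(sub$outcome %in% c("INEXCITABLE", "ERROR"))
    N <- sum(keep)
    blocked <- sub$outcome[keep] %in%
      c("BLOCK_NO_REENTRY", "REENTRY_NONSUSTAINED", "REENTRY_SUSTAINED")
    reentry <- sub$outcome[keep] %in%
      c("REENTRY_NONSUSTAINED", "REENTRY_SUSTAINED")
    sustained <- sub$outcome[keep] == "REENTRY_SUSTAINED"
    out <- sub[1, group_axes, drop = FALSE]
    out$N <- N
    out$n_excluded <- sum(!keep)
    out$p_block <- if (N > 0) mean(blocked) else NA_real_
    out$p_reentry <- if (N > 0) mean(reentry) else NA_real_
    out$p_sustained <- if (N > 0) mean(sustained) else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, out[group_axes]), , drop = FALSE]
}
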