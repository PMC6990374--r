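#' Outcome classes of an S1-S2 run
#' @export
OUTCOME_CLASSES <- c("NO_BLOCK", "BLOCK_NO_REENTRY", "REENTRY_NONSUSTAINED",
                     "REENTRY_SUSTAINED", "INEXCITABLE")

#' Activation / repolarization / APD maps for one beat
#'
#' Activation time is the first upward crossing of the activation threshold
#' inside the window; repolarization time is the first subsequent downward
#' crossing of the repolarization level. Nodes that never activate in the
#' window are masked (`NA`) in every map.
#'
#' @param rec a `vm_recording`.
#' @param window two-element time interval (ms) bracketing one beat.
#' @return object of class `field_maps`: matrices `at`, `rt`, `apd` of
#'   dimension (nx+1) x (ny+1), plus the window and grid.
#' @export
activation_repolarization_maps <- function(rec, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  grid <- rec$grid
  np <- (grid$nx + 1L) * (grid$ny + 1L)
  ev <- rec$events
  at <- rep(NA_real_, np)
  up <- ev[ev$dir == 1 & ev$time >= window[1] & ev$time < window[2], ]
  up <- up[order(up$time), ]
  first <- !duplicated(up$node)
  at[up$node[first]] <- up$time[first]

  rt <- rep(NA_real_, np)
  dn <- ev[ev$dir == -1 & ev$time >= window[1], ]
  dn <- dn[order(dn$time), ]
  ok <- !is.na(at[dn$node]) & dn$time > at[dn$node]
  dn <- dn[ok, ]
  first <- !duplicated(dn$node)
  rt[dn$node[first]] <- dn$time[first]

  dim(at) <- c(grid$nx + 1L, grid$ny + 1L)
  dim(rt) <- c(grid$nx + 1L, grid$ny + 1L)
  structure(list(at = at, rt = rt, apd = rt - at, window = window,
                 grid = grid),
            class = "field_maps")
}

#' Conduction velocity between two activated nodes
#'
#' Distance between the nodes divided by their activation-time difference;
#' the node pair should be aligned with the propagation direction.
#'
#' @param maps a `field_maps` object.
#' @param p1,p2 node indices (proximal, distal).
#' @return velocity in m/s (mm/ms).
#' @export
conduction_velocity <- function(maps, p1, p2) {
  grid <- maps$grid
  h <- grid$h_um / 1000
  npx <- grid$nx + 1L
  ij <- function(p) c((p - 1L) %% npx, (p - 1L) %/% npx)
  a <- ij(p1); b <- ij(p2)
  dist <- h * sqrt(sum((a - b)^2))
  t1 <- maps$at[p1]; t2 <- maps$at[p2]
  if (is.na(t1) || is.na(t2)) stop("both nodes must be activated")
  if (t2 <= t1) stop("non-causal pair: distal node activates first")
  dist / (t2 - t1)
}

#' Re-entry vulnerability index map
#'
#' For each activated node d, `RVI(d) = min over proximal neighbours p of
#' [rt(p) - at(d)]`, where "proximal" means `at(p) < at(d)` and p lies
#' within `pairing_radius_mm`. Small values flag wavefront-waveback
#' interaction (block substrate); negative values are the signature of
#' re-entrant re-excitation. Nodes with no qualifying neighbour are masked.
#'
#' @param maps a `field_maps` object.
#' @param pairing_radius_mm neighbourhood radius (mm).
#' @return matrix of RVI values (ms), dimension (nx+1) x (ny+1).
#' @export
rvi_map <- function(maps, pairing_radius_mm = 2) {
  grid <- maps$grid
  h <- grid$h_um / 1000
  r <- max(1L, floor(pairing_radius_mm / h))
  at <- maps$at
  rt <- maps$rt
  n1 <- nrow(at); n2 <- ncol(at)
  best <- matrix(Inf, n1, n2)
  shift <- function(M, di, dj) {
    out <- matrix(NA_real_, n1, n2)
    si <- max(1, 1 - di):min(n1, n1 - di)
    sj <- max(1, 1 - dj):min(n2, n2 - dj)
    out[si + di, sj + dj] <- M[si, sj]
    out
  }
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    if ((di^2 + dj^2) * h^2 > pairing_radius_mm^2 + 1e-9) next
    atp <- shift(at, di, dj)
    rtp <- shift(rt, di, dj)
    cand <- ifelse(!is.na(atp) & !is.na(at) & atp < at & !is.na(rtp),
                   rtp - at, Inf)
    best <- pmin(best, cand)
  }
  best[!is.finite(best)] <- NA_real_
  best
}

# first activation per node within a window (vector over all nodes)
first_activation <- function(rec, window) {
  np <- (rec$grid$nx + 1L) * (rec$grid$ny + 1L)
  ev <- rec$events
  up <- ev[ev$dir == 1 & ev$time >= window[1] & ev$time < window[2], ]
  up <- up[order(up$time), ]
  first <- !duplicated(up$node)
  at <- rep(NA_real_, np)
  at[up$node[first]] <- up$time[first]
  at
}

#' Classify the outcome of an S1-S2 run
#'
#' Applies, in order: (1) `INEXCITABLE` if the S1 train never activates
#' the channel's centre cross-section band, which lies beyond
#' electrotonic reach of either mouth - the pathway carries no propagated
#' activation; (2) re-entry detection - a sentinel node (healthy
#' tissue 5 mm beyond either isthmus mouth) that re-activates later than
#' 50 ms after the last stimulus-driven wavefront has cleared the sheet
#' counts one re-entrant cycle per re-activation, `REENTRY_SUSTAINED` iff
#' more than one cycle; (3) `BLOCK_NO_REENTRY` if the minimum RVI of the S2
#' beat falls below `block_fraction` of the mean healthy-tissue APD of the
#' last S1 beat and the S2 wavefront fails to transit the isthmus; else
#' (4) `NO_BLOCK`.
#'
#' @param rec a `vm_recording` produced by [run_s1s2()].
#' @param pairing_radius_mm RVI pairing radius (mm).
#' @param block_fraction RVI threshold as a fraction of mean APD.
#' @param clear_window window after S2 (ms) whose first activations are
#'   attributed to the stimulus-driven S2 wavefront.
#' @param reentry_gap quiet interval (ms) required between the cleared S2
#'   wavefront and a re-activation before it counts as re-entrant.
#' @return list with `outcome`, `n_cycles`, `mean_apd`, `min_rvi`,
#'   `s2_transit`, `t_clear`.
#' @export
classify_outcome <- function(rec, pairing_radius_mm = 2,
                             block_fraction = 0.30, clear_window = 400,
                             reentry_gap = 50) {
  pr <- rec$protocol
  if (is.null(pr)) stop("recording carries no S1-S2 protocol metadata")
  sites <- pr$sites
  t_s2 <- pr$t_s2
  bcl <- pr$spec$bcl
  t_s1_last <- pr$s1_onsets[length(pr$s1_onsets)]
  ev <- rec$events
  setup <- rec$setup

  # ordered first arrival across the channel cross-section bands: the
  # wavefront conducted through the channel bottom-up
  band_transit <- function(at) {
    if (is.null(sites$entry_band)) return(NA)
    a <- vapply(list(sites$entry_band, sites$centre_band, sites$exit_band),
                function(b) {
                  v <- at[b]
                  if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
                }, numeric(1))
    all(!is.na(a)) && !is.unsorted(a, strictly = FALSE)
  }

  # (1) inexcitable isthmus: S1 never activates the channel's centre
  # band, which lies beyond electrotonic reach of either mouth - so the
  # pathway carries no propagated activation from either end. (The mouths
  # themselves can be driven above threshold electrotonically by the
  # adjacent healthy wavefront even in a completely inexcitable channel.)
  bz_nodes <- which(setup$bz_mask)
  if (length(bz_nodes) > 0) {
    bz_active <- any(ev$dir == 1 & ev$time < t_s2 & ev$node %in% bz_nodes)
    at_s1 <- first_activation(rec, c(t_s1_last, t_s2))
    centre_active <- is.null(sites$centre_band) ||
      any(!is.na(at_s1[sites$centre_band]))
    if (!bz_active || !centre_active)
      return(list(outcome = "INEXCITABLE", n_cycles = 0L,
                  mean_apd = NA_real_, min_rvi = NA_real_,
                  s2_transit = FALSE, t_clear = NA_real_))
  }

  # mean APD of healthy tissue on the last S1 beat
  maps_s1 <- activation_repolarization_maps(rec, c(t_s1_last, t_s2))
  healthy <- setup$active_mask & !setup$bz_mask
  mean_apd <- mean(maps_s1$apd[healthy], na.rm = TRUE)

  # stimulus-driven S2 wavefront clearance time
  at_s2 <- first_activation(rec, c(t_s2, t_s2 + clear_window))
  t_clear <- if (any(!is.na(at_s2))) max(at_s2, na.rm = TRUE) else t_s2

  # re-entrant cycles at the sentinels
  sent <- c(sites$prox_sentinel, sites$dist_sentinel)
  n_cycles <- 0L
  if (length(sent) > 0) {
    n_cycles <- max(vapply(sent, function(p) {
      sum(ev$node == p & ev$dir == 1 & ev$time > t_clear + reentry_gap)
    }, integer(1)))
  }

  # S2 transit through the isthmus and the RVI block criterion. Transit
  # must be direction-resolved: the entry, centre and exit of the channel
  # activated in that order by the S2 wavefront. (A blocked beat whose
  # around-scar wave re-enters the channel from the distal mouth also
  # activates the channel, but top-down.)
  maps_s2 <- activation_repolarization_maps(rec, c(t_s2, rec$t_stop))
  # RVI pairs the premature wavefront's arrival with the recovery of the
  # tissue just proximal. Nodes the S2 beat never re-excites still carry
  # their recovery time from the S1 beat: backfill their activation and
  # repolarization from the S1 maps, so complete entrance block (blocked
  # channel never reactivated) is visible to the metric.
  fill <- is.na(maps_s2$at)
  maps_eval <- maps_s2
  maps_eval$at[fill] <- maps_s1$at[fill]
  maps_eval$rt[fill] <- maps_s1$rt[fill]
  rvi <- rvi_map(maps_eval, pairing_radius_mm)
  min_rvi <- if (any(!is.na(rvi))) min(rvi, na.rm = TRUE) else NA_real_
  s2_transit <- if (!is.null(sites$entry_band)) {
    isTRUE(band_transit(at_s2))
  } else {
    detect_capture(rec, t_s2, sites$top_center, pr$spec$capture_window)
  }
  blocked <- !is.na(min_rvi) && !is.na(mean_apd) &&
    min_rvi < block_fraction * mean_apd && !s2_transit

  outcome <- if (n_cycles > 1L) "REENTRY_SUSTAINED"
  else if (n_cycles == 1L) "REENTRY_NONSUSTAINED"
  else if (blocked) "BLOCK_NO_REENTRY"
  else "NO_BLOCK"

  list(outcome = outcome, n_cycles = n_cycles, mean_apd = mean_apd,
       min_rvi = min_rvi, s2_transit = s2_transit, t_clear = t_clear)
}
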