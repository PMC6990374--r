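#' Cell parameter set for the TT06 endocardial model
#'
#' Conductance multipliers are dimensionless scalings of the published
#' maximal conductances; `1.0` leaves the current unchanged. The membrane
#' capacitance per unit area `cm` (uF/cm^2) enters the tissue-level
#' conductivity-to-diffusivity conversion; membrane kinetics are expressed
#' in the model's native pA/pF current scale.
#'
#' @param ina_scale multiplier on the fast sodium conductance GNa.
#' @param gkr_scale multiplier on the rapid delayed-rectifier conductance GKr.
#' @param gks_scale multiplier on the slow delayed-rectifier conductance GKs.
#' @param cm membrane capacitance per unit area (uF/cm^2).
#' @param subtype cell subtype tag; only the endocardial variant is provided.
#' @return an object of class `cell_params`.
#' @export
cell_params <- function(ina_scale = 1.0, gkr_scale = 1.0, gks_scale = 1.0,
                        cm = 1.0, subtype = "endocardial") {
  stopifnot(ina_scale >= 0, gkr_scale >= 0, gks_scale >= 0, cm > 0)
  subtype <- match.arg(subtype, "endocardial")
  structure(list(ina_scale = ina_scale, gkr_scale = gkr_scale,
                 gks_scale = gks_scale, cm = cm, subtype = subtype,
                 variant = "ten Tusscher-Panfilov 2006, endocardial"),
            class = "cell_params")
}

#' Border-zone remodeling specification
#'
#' Two remodeling arms are supported: `prolonged_apd` reduces GKr to 20% and
#' GKs to 30% of control, and `reduced_ina` scales GNa by `ina_scale`.
#' `combined` applies both; `none` leaves the cell unremodeled.
#'
#' @param mode one of `"none"`, `"prolonged_apd"`, `"reduced_ina"`,
#'   `"combined"`.
#' @param ina_scale GNa multiplier in `(0, 1]`, used by `reduced_ina` and
#'   `combined`.
#' @return an object of class `remodeling_spec` with the resulting
#'   `ina_scale`, `gkr_scale`, `gks_scale`.
#' @export
remodeling_spec <- function(mode = c("none", "prolonged_apd", "reduced_ina",
                                     "combined"),
                            ina_scale = 1.0) {
  mode <- match.arg(mode)
  stopifnot(ina_scale > 0, ina_scale <= 1)
  gkr <- 1.0
  gks <- 1.0
  ina <- 1.0
  if (mode %in% c("prolonged_apd", "combined")) {
    gkr <- 0.20
    gks <- 0.30
  }
  if (mode %in% c("reduced_ina", "combined")) ina <- ina_scale
  structure(list(mode = mode, ina_scale = ina, gkr_scale = gkr,
                 gks_scale = gks),
            class = "remodeling_spec")
}

#' Apply a remodeling specification to a cell parameter set
#'
#' @param params a [cell_params()] object (the control cell).
#' @param remodeling a [remodeling_spec()] object.
#' @return the remodeled `cell_params`.
#' @export
apply_remodeling <- function(params, remodeling) {
  stopifnot(inherits(params, "cell_params"),
            inherits(remodeling, "remodeling_spec"))
  cell_params(ina_scale = params$ina_scale * remodeling$ina_scale,
              gkr_scale = params$gkr_scale * remodeling$gkr_scale,
              gks_scale = params$gks_scale * remodeling$gks_scale,
              cm = params$cm, subtype = params$subtype)
}

#' Initial (quiescent) state of the TT06 endocardial model
#'
#' Membrane voltage `vm` (mV) followed by the gating/concentration vector.
#' @return named numeric vector of length 19.
#' @export
cell_initial_state <- function() {
  tt06_init_state_cpp()
}

check_cell_state <- function(state) {
  if (length(state) != 19L)
    stop("cell state must have 19 entries (vm + 18 gating/concentration variables)")
  bad <- which(!is.finite(state))
  if (length(bad) > 0)
    stop(sprintf("invalid cell state: variable '%s' is non-finite",
                 tt06_state_names_cpp()[bad[1]]))
  invisible(state)
}

#' Advance a single cell by explicit steps
#'
#' Advances the state by `n_steps` steps of size `dt` under a constant
#' stimulus current density. Hodgkin-Huxley gates use the Rush-Larsen
#' exponential update (bounded in `[0, 1]` by construction); concentrations
#' advance by forward Euler.
#'
#' @param state numeric state vector as returned by [cell_initial_state()].
#' @param params a [cell_params()] object.
#' @param istim stimulus current density (uA/cm^2, depolarizing positive).
#' @param dt time step (ms), in `(0, 0.1]`.
#' @param n_steps number of steps to take.
#' @return the advanced state vector.
#' @export
step_cell <- function(state, params = cell_params(), istim = 0, dt = 0.02,
                      n_steps = 1L) {
  check_cell_state(state)
  stopifnot(dt > 0, dt <= 0.1, n_steps >= 1)
  cell_steps_cpp(as.numeric(state), params$ina_scale, params$gkr_scale,
                 params$gks_scale, istim, dt, as.integer(n_steps))
}

#' Run a single-cell pacing train
#'
#' @param params a [cell_params()] object.
#' @param frequency pacing frequency (Hz).
#' @param n_beats number of beats.
#' @param state0 starting state; defaults to the quiescent model state.
#' @param dt time step (ms).
#' @param stim_amp,stim_dur stimulus amplitude (uA/cm^2) and duration (ms).
#' @param sample_dt trace sampling interval (ms).
#' @return list with `time_ms`, `vm_mV`, `state` (final), and the stimulus
#'   onset times.
#' @export
pace_cell <- function(params = cell_params(), frequency = 2.0, n_beats = 100L,
                      state0 = cell_initial_state(), dt = 0.02,
                      stim_amp = 100, stim_dur = 1, sample_dt = 1) {
  stopifnot(frequency > 0, n_beats >= 1)
  bcl <- 1000 / frequency
  onsets <- (seq_len(n_beats) - 1) * bcl
  out <- cell_run_cpp(as.numeric(state0), params$ina_scale, params$gkr_scale,
                      params$gks_scale, onsets, stim_dur, stim_amp, dt, 0,
                      n_beats * bcl, sample_dt)
  out$stim_onsets <- onsets
  out
}

#' Pace a cell to its steady state
#'
#' Paces the model at `frequency` for `n_beats` beats (defaults: 2 Hz, 100
#' beats) and returns the end-of-train state plus a per-beat APD90 trace for
#' diagnostics. A beat whose peak voltage stays below 0 mV raises a
#' no-capture error naming the beat.
#'
#' @inheritParams pace_cell
#' @param apd_fraction repolarization fraction used for the APD diagnostic.
#' @return list with `state` (end of beat `n_beats`), `apd_ms` (per-beat
#'   APD), and `frequency`.
#' @export
pace_to_steady <- function(params = cell_params(), frequency = 2.0,
                           n_beats = 100L, dt = 0.02, stim_amp = 100,
                           stim_dur = 1, apd_fraction = 0.9) {
  run <- pace_cell(params, frequency, n_beats, dt = dt, stim_amp = stim_amp,
                   stim_dur = stim_dur, sample_dt = 1)
  bcl <- 1000 / frequency
  # per-beat capture check on the trace
  tm <- run$time_ms
  vm <- run$vm_mV
  for (b in seq_len(n_beats)) {
    win <- tm >= (b - 1) * bcl & tm < b * bcl
    if (max(vm[win]) < 0)
      stop(sprintf("no-capture: beat %d did not fire during steady-state pacing", b))
  }
  apd <- measure_apd(data.frame(time_ms = tm, vm_mV = vm),
                     repolarization_fraction = apd_fraction)
  list(state = run$state, apd_ms = apd, frequency = frequency,
       n_beats = n_beats)
}

# memoised steady states keyed by cell parameters; pacing a cell for 100
# beats is cheap but is requested repeatedly by sweeps and tests
steady_state_cached <- function(params, frequency = 2.0, n_beats = 100L,
                                dt = 0.02) {
  key <- paste0("ss:", paste(signif(c(params$ina_scale, params$gkr_scale,
                                      params$gks_scale, frequency,
                                      n_beats, dt), 10), collapse = "_"))
  if (!is.null(.infarctsim_cache[[key]])) return(.infarctsim_cache[[key]])
  val <- pace_to_steady(params, frequency, n_beats, dt = dt)
  assign(key, val, envir = .infarctsim_cache)
  val
}

#' Measure action potential durations from a voltage trace
#'
#' APD is the time between the upward and the subsequent downward crossing
#' of the level `Vrest + (1 - fraction) * (Vpeak - Vrest)`, where `Vrest`
#' and `Vpeak` are the trace minimum and maximum. One value is returned per
#' detected beat; a trace with no upstroke yields a zero-length result.
#' Crossing times are refined by linear interpolation between samples.
#'
#' @param trace data frame with columns `time_ms` and `vm_mV` (or a list
#'   with those elements).
#' @param repolarization_fraction repolarization fraction in `(0, 1)`;
#'   default 0.9 (APD90).
#' @return numeric vector of APDs (ms), one per beat.
#' @export
measure_apd <- function(trace, repolarization_fraction = 0.9) {
  stopifnot(repolarization_fraction > 0, repolarization_fraction < 1)
  tm <- trace$time_ms
  vm <- trace$vm_mV
  stopifnot(length(tm) == length(vm), length(tm) >= 2)
  vrest <- min(vm)
  vpeak <- max(vm)
  level <- vrest + (1 - repolarization_fraction) * (vpeak - vrest)
  below <- vm < level
  up <- which(below[-length(below)] & !below[-1])
  down <- which(!below[-length(below)] & below[-1])
  if (length(up) == 0) return(numeric(0))
  cross_t <- function(i, lev) {
    # linear interpolation within sample interval i -> i+1
    tm[i] + (tm[i + 1] - tm[i]) * (lev - vm[i]) / (vm[i + 1] - vm[i])
  }
  apd <- numeric(0)
  for (i in up) {
    jn <- down[down >= i]
    if (length(jn) == 0) break
    apd <- c(apd, cross_t(jn[1], level) - cross_t(i, level))
  }
  apd
}

#' Maximal upstroke velocity of a voltage trace
#'
#' @param trace data frame with `time_ms`, `vm_mV`.
#' @return max dV/dt (mV/ms) over the trace.
#' @export
max_upstroke_velocity <- function(trace) {
  dv <- diff(trace$vm_mV) / diff(trace$time_ms)
  max(dv)
}

#' Write a single-cell trace as CSV
#'
#' @param trace list/data frame with `time_ms`, `vm_mV`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_ms = trace$time_ms, vm_mV = trace$vm_mV),
            path, row.names = FALSE)
  invisible(path)
}
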