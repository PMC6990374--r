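#' Derivative-form right-hand side of the TT06 endocardial model
#'
#' A plain-R transcription of the published model equations in the form
#' `deSolve` expects, used as an independent integration path (adaptive
#' stiff solver, no lookup tables, no Rush-Larsen update) for validating
#' the production stepper.
#'
#' @param t time (ms); unused except by the solver.
#' @param y named state vector (vm + 18 gating/concentration variables).
#' @param parms list with `ina_scale`, `gkr_scale`, `gks_scale`, `istim`
#'   (uA/cm^2, depolarizing positive).
#' @return list of derivatives, as required by [deSolve::ode()].
#' @export
tt06_rhs <- function(t, y, parms) {
  Rgas <- 8314.472; Temp <- 310; Frdy <- 96485.3415
  RTF <- Rgas * Temp / Frdy; FRT <- 1 / RTF
  Ko <- 5.4; Nao <- 140; Cao <- 2
  Vc <- 0.016404; Vsr <- 0.001094; Vss <- 0.00005468; Cap <- 0.185
  Bufc <- 0.2; Kbufc <- 0.001; Bufsr <- 10; Kbufsr <- 0.3
  Bufss <- 0.4; Kbufss <- 0.00025
  Vmaxup <- 0.006375; Kup <- 0.00025
  Vrel <- 0.102; Vleak <- 0.00036; Vxfer <- 0.0038
  k1p <- 0.15; k2p <- 0.045; k3 <- 0.060; k4 <- 0.005
  EC <- 1.5; maxsr <- 2.5; minsr <- 1
  GNa <- 14.838; GK1 <- 5.405; Gto <- 0.073; GKr <- 0.153; GKs <- 0.392
  GCaL <- 0.0000398; GbNa <- 0.00029; GbCa <- 0.000592
  GpCa <- 0.1238; KpCa <- 0.0005; GpK <- 0.0146; pKNa <- 0.03
  PNaK <- 2.724; KmK <- 1; KmNa <- 40
  kNaCa <- 1000; ksat <- 0.1; alp <- 2.5; gam <- 0.35
  KmNai <- 87.5; KmCa <- 1.38

  V <- y[1]; m <- y[2]; h <- y[3]; j <- y[4]; d <- y[5]; f <- y[6]
  f2 <- y[7]; fcass <- y[8]; r <- y[9]; s <- y[10]; xr1 <- y[11]
  xr2 <- y[12]; xs <- y[13]; Rq <- y[14]; Cai <- y[15]; CaSS <- y[16]
  CaSR <- y[17]; Nai <- y[18]; Ki <- y[19]

  EK <- RTF * log(Ko / Ki)
  ENa <- RTF * log(Nao / Nai)
  EKs <- RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai))
  ECa <- 0.5 * RTF * log(Cao / Cai)

  INa <- GNa * parms$ina_scale * m^3 * h * j * (V - ENa)
  x <- 2 * (V - 15) * FRT
  drv <- if (abs(x) < 1e-7) {
    GCaL * 2 * Frdy * (0.25 * CaSS - Cao)
  } else {
    GCaL * 4 * (V - 15) * Frdy * FRT * (0.25 * CaSS * exp(x) - Cao) / (exp(x) - 1)
  }
  ICaL <- d * f * f2 * fcass * drv
  Ito <- Gto * r * s * (V - EK)
  IKr <- GKr * parms$gkr_scale * xr1 * xr2 * (V - EK)
  IKs <- GKs * parms$gks_scale * xs^2 * (V - EKs)
  aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bK1 <- (3 * exp(0.0002 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  IK1 <- GK1 * aK1 / (aK1 + bK1) * (V - EK)
  INaCa <- kNaCa *
    (exp(gam * V * FRT) * Nai^3 * Cao -
       exp((gam - 1) * V * FRT) * Nao^3 * Cai * alp) /
    ((KmNai^3 + Nao^3) * (KmCa + Cao) * (1 + ksat * exp((gam - 1) * V * FRT)))
  INaK <- PNaK * Ko * Nai /
    ((Ko + KmK) * (Nai + KmNa) *
       (1 + 0.1245 * exp(-0.1 * V * FRT) + 0.0353 * exp(-V * FRT)))
  IpCa <- GpCa * Cai / (Cai + KpCa)
  IpK <- GpK * (V - EK) / (1 + exp((25 - V) / 5.98))
  IbNa <- GbNa * (V - ENa)
  IbCa <- GbCa * (V - ECa)

  istim <- parms$istim
  Iion <- INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa + IpK +
    IbNa + IbCa
  dV <- istim - Iion

  # gate kinetics
  minf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  taum <- (1 / (1 + exp((-60 - V) / 5))) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  hinf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V >= -40) {
    ah <- 0; bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 310000 * exp(0.3485 * V)
  }
  tauh <- 1 / (ah + bh)
  if (V >= -40) {
    aj <- 0; bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    aj <- (-25428 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  tauj <- 1 / (aj + bj)
  dinf <- 1 / (1 + exp((-8 - V) / 7.5))
  taud <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) *
    (1.4 / (1 + exp((V + 5) / 5))) + 1 / (1 + exp((50 - V) / 20))
  finf <- 1 / (1 + exp((V + 20) / 7))
  tauf <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tauf2 <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  xcass <- (CaSS / 0.05)^2
  fcassinf <- 0.6 / (1 + xcass) + 0.4
  taufcass <- 80 / (1 + xcass) + 2
  rinf <- 1 / (1 + exp((20 - V) / 6))
  taur <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  sinf <- 1 / (1 + exp((V + 28) / 5))          # endocardial
  taus <- 1000 * exp(-(V + 67)^2 / 1000) + 8   # endocardial
  xr1inf <- 1 / (1 + exp((-26 - V) / 7))
  tauxr1 <- (450 / (1 + exp((-45 - V) / 10))) * (6 / (1 + exp((V + 30) / 11.5)))
  xr2inf <- 1 / (1 + exp((V + 88) / 24))
  tauxr2 <- (3 / (1 + exp((-60 - V) / 20))) * (1.12 / (1 + exp((V - 60) / 20)))
  xsinf <- 1 / (1 + exp((-5 - V) / 14))
  tauxs <- (1400 / sqrt(1 + exp((5 - V) / 6))) * (1 / (1 + exp((V - 35) / 15))) + 80

  # calcium subsystem
  kcasr <- maxsr - (maxsr - minsr) / (1 + (EC / CaSR)^2)
  k1 <- k1p / kcasr
  k2 <- k2p * kcasr
  dRq <- k4 * (1 - Rq) - k2 * CaSS * Rq
  O <- k1 * CaSS^2 * Rq / (k3 + k1 * CaSS^2)
  Irel <- Vrel * O * (CaSR - CaSS)
  Ileak <- Vleak * (CaSR - Cai)
  Iup <- Vmaxup / (1 + Kup^2 / Cai^2)
  Ixfer <- Vxfer * (CaSS - Cai)
  bc <- 1 / (1 + Bufc * Kbufc / (Cai + Kbufc)^2)
  bsr <- 1 / (1 + Bufsr * Kbufsr / (CaSR + Kbufsr)^2)
  bss <- 1 / (1 + Bufss * Kbufss / (CaSS + Kbufss)^2)

  dCai <- bc * (-(IbCa + IpCa - 2 * INaCa) * Cap / (2 * Vc * Frdy) -
                  (Iup - Ileak) * (Vsr / Vc) + Ixfer)
  dCaSR <- bsr * (Iup - Irel - Ileak)
  dCaSS <- bss * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                    ICaL * Cap / (2 * Vss * Frdy))
  dNai <- -(INa + IbNa + 3 * INaK + 3 * INaCa) * Cap / (Vc * Frdy)
  dKi <- -(-istim + IK1 + Ito + IKr + IKs - 2 * INaK + IpK) * Cap / (Vc * Frdy)

  # j shares its steady state with h
  list(c(dV,
         (minf - m) / taum, (hinf - h) / tauh, (hinf - j) / tauj,
         (dinf - d) / taud, (finf - f) / tauf, (f2inf - f2) / tauf2,
         (fcassinf - fcass) / taufcass, (rinf - r) / taur, (sinf - s) / taus,
         (xr1inf - xr1) / tauxr1, (xr2inf - xr2) / tauxr2,
         (xsinf - xs) / tauxs, dRq, dCai, dCaSS, dCaSR, dNai, dKi))
}

#' Reference integration of the TT06 model with an adaptive stiff solver
#'
#' Integrates [tt06_rhs()] with `deSolve::ode` (lsoda), splitting the time
#' axis at stimulus edges so the discontinuous stimulus is handled exactly.
#'
#' @param state0 initial state vector.
#' @param params a [cell_params()] object.
#' @param stim_onsets stimulus onset times (ms).
#' @param stim_dur,stim_amp stimulus duration (ms) and amplitude (uA/cm^2).
#' @param t_end end time (ms).
#' @param sample_dt output sampling interval (ms).
#' @param rtol,atol solver tolerances.
#' @return data frame with `time_ms`, `vm_mV`, plus all state columns.
#' @export
reference_integrate <- function(state0, params = cell_params(),
                                stim_onsets = numeric(), stim_dur = 1,
                                stim_amp = 100, t_end = 1000, sample_dt = 1,
                                rtol = 1e-8, atol = 1e-8) {
  edges <- sort(unique(c(0, stim_onsets, stim_onsets + stim_dur, t_end)))
  edges <- edges[edges >= 0 & edges <= t_end]
  if (edges[length(edges)] < t_end) edges <- c(edges, t_end)
  y <- as.numeric(state0)
  nm <- tt06_state_names_cpp()
  out_t <- 0
  out_y <- matrix(y, nrow = 1)
  for (k in seq_len(length(edges) - 1)) {
    t0 <- edges[k]; t1 <- edges[k + 1]
    on <- any(stim_onsets <= t0 + 1e-9 & t0 < stim_onsets + stim_dur - 1e-9)
    parms <- list(ina_scale = params$ina_scale, gkr_scale = params$gkr_scale,
                  gks_scale = params$gks_scale,
                  istim = if (on) stim_amp else 0)
    times <- sort(unique(c(seq(t0, t1, by = sample_dt), t1)))
    sol <- deSolve::ode(y = y, times = times, func = tt06_rhs, parms = parms,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[-1, , drop = FALSE]
    out_t <- c(out_t, keep[, 1])
    out_y <- rbind(out_y, keep[, -1, drop = FALSE])
  }
  df <- as.data.frame(out_y)
  names(df) <- nm
  data.frame(time_ms = out_t, vm_mV = df$vm, df[, -1, drop = FALSE])
}
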