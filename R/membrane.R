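## Phenomenological two-variable membrane model (Mitchell-Schaeffer class)
## with per-region action-potential-duration variants.  The transmembrane
## potential is simulated in normalized units v in [0, 1] and mapped to
## millivolts through V = V_rest + (V_peak - V_rest) * v; currents are
## capacitance-normalized (pA/pF = mV/ms with C_m = 1).

#' Default per-region APD90 targets (ms)
#'
#' The mitral-valve region carries the shortest action potential (170 ms);
#' all other regions are graded upward so that full atrial activation always
#' completes within one action potential.
#' @return named numeric vector.
#' @export
default_apd_targets <- function() {
  c(MV_RING = 170, TV_RING = 180, LAA = 185, PV_LSPV = 185, PV_LIPV = 185,
    PV_RSPV = 185, PV_RIPV = 185, LA_WALL = 190, SAN = 190, LA_POST = 195,
    SVC = 200, IVC = 200, CS_SLEEVE = 200, BRIDGE_PROX = 200,
    BRIDGE_DIST = 200, RAA = 205, RA_WALL = 210, RA_SEPTUM = 210, FO = 210,
    BB_R = 220, BB_L = 220, CT = 230)
}

#' Construct the membrane model
#'
#' @param apd_targets named APD90 targets per region variant (ms).
#' @param tau_in,tau_out,tau_open excitation/repolarization/recovery time
#'   constants (ms).
#' @param v_gate dimensionless activation gate threshold.
#' @param V_rest,V_peak resting and peak potential (mV).
#' @return object of class `membrane_model`.  Per-variant `tau_close` values
#'   are calibrated lazily (and cached) so that the paced single-cell APD90
#'   matches each target within 2 ms.
#' @export
membrane_model <- function(apd_targets = default_apd_targets(),
                           tau_in = 0.3, tau_out = 6, tau_open = 120,
                           v_gate = 0.13, V_rest = -80, V_peak = 20) {
  structure(list(
    name = "mitchell-schaeffer",
    state_dim = 2L,
    apd_targets = apd_targets,
    tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
    v_gate = v_gate, V_rest = V_rest, V_peak = V_peak,
    C_m = 1,
    cache = new.env(parent = emptyenv())
  ), class = "membrane_model")
}

## Single-cell paced simulation; returns the full (t, v, w) arrays.
ms_single_cell <- function(model, tau_close, BCL, n_beats, dt = 0.02,
                           stim_amp = 28, stim_dur = 2) {
  amp_v <- stim_amp / (model$V_peak - model$V_rest)  # normalized 1/ms
  nt <- ceiling(n_beats * BCL / dt)
  t <- (seq_len(nt) - 1) * dt
  v <- numeric(nt); w <- numeric(nt)
  vi <- 0; wi <- 1
  for (i in seq_len(nt)) {
    ti <- t[i]
    phase <- ti %% BCL
    stim <- if (phase < stim_dur) amp_v else 0
    dv <- wi * vi^2 * (1 - vi) / model$tau_in - vi / model$tau_out + stim
    dw <- if (vi < model$v_gate) (1 - wi) / model$tau_open else -wi / tau_close
    vi <- vi + dt * dv
    wi <- min(1, max(0, wi + dt * dw))
    v[i] <- vi; w[i] <- wi
  }
  list(t = t, v = v, w = w, dt = dt, BCL = BCL)
}

## APD90 of the last beat: max-upstroke-velocity time to 90% repolarization.
ms_apd90 <- function(sim, model) {
  BCL <- sim$BCL
  last_start <- (max(0, floor(max(sim$t) / BCL) - 1)) * BCL
  sel <- sim$t >= last_start & sim$t < last_start + BCL
  t <- sim$t[sel]; v <- sim$v[sel]
  if (max(v) < model$v_gate) stimulus_error("no upstroke elicited")
  dv <- diff(v) / sim$dt
  iup <- which.max(dv)
  t_up <- t[iup]
  vmax <- max(v)
  vmin <- min(v[seq_len(iup)])
  v90 <- vmax - 0.9 * (vmax - vmin)
  after <- which(t > t[which.max(v)] & v <= v90)
  if (!length(after)) stimulus_error("no repolarization within the beat")
  i2 <- after[1]
  ## linear interpolation of the downward crossing
  t_cross <- t[i2 - 1] + (v[i2 - 1] - v90) / (v[i2 - 1] - v[i2]) * sim$dt
  t_cross - t_up
}

## Calibrated tau_close for one APD target (cached secant iteration).
ms_tau_close <- function(model, region, BCL = 500, n_beats = 3) {
  key <- sprintf("%s|%g|%g", region, BCL, n_beats)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  target <- model$apd_targets[[region]]
  if (is.null(target)) config_error(paste("no APD target for region", region))
  apd_of <- function(tc) ms_apd90(ms_single_cell(model, tc, BCL, n_beats), model)
  x0 <- target / 1.30; x1 <- target / 1.45
  f0 <- apd_of(x0) - target; f1 <- apd_of(x1) - target
  for (i in 1:8) {
    if (abs(f1) < 0.25) break
    x2 <- x1 - f1 * (x1 - x0) / (f1 - f0)
    x2 <- max(10, min(500, x2))
    x0 <- x1; f0 <- f1
    x1 <- x2; f1 <- apd_of(x1) - target
  }
  model$cache[[key]] <- x1
  x1
}

#' Steady-state single-cell APD90 of a region variant
#'
#' Paces a single cell of the requested regional variant and measures APD90
#' on the last beat as the interval from maximum upstroke velocity to 90%
#' repolarization.
#'
#' @param model a [membrane_model()].
#' @param region region variant name (e.g. `"MV_RING"`).
#' @param BCL basic cycle length (ms), default 500.
#' @param n_beats number of paced beats (>= 2; default 5 for steady state).
#' @param stim_amp stimulus amplitude (pA/pF); 0 raises a stimulus error.
#' @return APD90 in ms.
#' @export
single_cell_apd <- function(model, region, BCL = 500, n_beats = 5,
                            stim_amp = 28) {
  if (n_beats < 2) parameter_error("n_beats must be >= 2")
  tc <- ms_tau_close(model, region, BCL = 500, n_beats = 3)
  sim <- ms_single_cell(model, tc, BCL, n_beats, stim_amp = stim_amp)
  ms_apd90(sim, model)
}

#' Stereotyped action-potential template of a region variant
#'
#' Last paced beat of the calibrated single-cell model, sampled on a uniform
#' grid and expressed in mV; time 0 is anchored at the upward -40 mV
#' crossing of the upstroke (so templates compose with activation maps).
#'
#' @param model a [membrane_model()].
#' @param region region variant name.
#' @param BCL pacing cycle length (ms).
#' @param dt_out output sampling step (ms).
#' @return list with `t` (ms) and `V` (mV).
#' @export
ap_template <- function(model, region, BCL = 500, dt_out = 1) {
  key <- sprintf("tpl|%s|%g|%g", region, BCL, dt_out)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  tc <- ms_tau_close(model, region)
  sim <- ms_single_cell(model, tc, BCL, n_beats = 3)
  last_start <- 2 * BCL
  tt <- seq(0, BCL - dt_out, by = dt_out)
  v <- stats::approx(sim$t - last_start, sim$v, xout = tt, rule = 2)$y
  V <- model$V_rest + (model$V_peak - model$V_rest) * v
  ## re-anchor time 0 at the upward -40 mV crossing so that an activation
  ## map shifted through this template round-trips through compute_lat()
  thr <- -40
  i2 <- which(V >= thr)[1]
  t_c <- if (is.na(i2) || i2 == 1) 0 else {
    tt[i2 - 1] + (thr - V[i2 - 1]) / (V[i2] - V[i2 - 1]) * dt_out
  }
  Vs <- stats::approx(tt - t_c, V, xout = tt, rule = 2)$y
  tpl <- list(t = tt, V = Vs)
  model$cache[[key]] <- tpl
  tpl
}

#' Verify the resting state of the membrane model
#'
#' At (v, w) = (0, 1) both state derivatives vanish identically.
#' @param model a [membrane_model()].
#' @return max absolute derivative (mV/ms) at rest.
#' @export
resting_derivative <- function(model) {
  dv <- 1 * 0^2 * (1 - 0) / model$tau_in - 0 / model$tau_out
  abs(dv) * (model$V_peak - model$V_rest)
}
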