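## Monodomain reaction-diffusion solver on the triangulated surface:
## linear (P1) finite elements with per-triangle anisotropic conductivity,
## operator splitting (explicit membrane update, implicit backward-Euler
## diffusion with mass lumping) and natural zero-flux boundaries.
## Node coordinates are mm; assembly converts to cm so that diffusivities
## sigma/C_m are cm^2/ms.

#' Assemble lumped mass vector and stiffness matrix
#'
#' @param mesh an annotated `atrial_mesh`.
#' @param cond a `conductivity_field`.
#' @param intracellular assemble with the intracellular tensor.
#' @return list `M` (lumped mass, cm^2) and `K` (sparse stiffness,
#'   sigma-weighted, cm^2/ms when divided by C_m).
#' @export
assemble_monodomain <- function(mesh, cond, intracellular = FALSE) {
  tri <- mesh$triangles
  p <- mesh$nodes / 10  # cm
  geo <- triangle_normals_areas(p, tri)
  A <- geo$areas
  n <- geo$normals
  p1 <- p[tri[, 1], , drop = FALSE]
  p2 <- p[tri[, 2], , drop = FALSE]
  p3 <- p[tri[, 3], , drop = FALSE]
  ## in-plane P1 basis gradients: grad phi_i = (n x e_opp) / (2A)
  g1 <- rowcross(n, p3 - p2) / (2 * A)
  g2 <- rowcross(n, p1 - p3) / (2 * A)
  g3 <- rowcross(n, p2 - p1) / (2 * A)
  f <- cond$fiber
  tdir <- rowcross(n, f)
  sl <- if (intracellular) cond$sigma_i_l else cond$sigma_l
  st <- if (intracellular) cond$sigma_i_t else cond$sigma_t
  ## D g = sl (f.g) f + st (t.g) t
  apply_D <- function(g) {
    f * (sl * rowSums(f * g)) + tdir * (st * rowSums(tdir * g))
  }
  Dg <- list(apply_D(g1), apply_D(g2), apply_D(g3))
  G <- list(g1, g2, g3)
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, a]
    jj[[k]] <- tri[, b]
    xx[[k]] <- A * rowSums(G[[a]] * Dg[[b]])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nrow(p), nrow(p)))
  M <- numeric(nrow(p))
  for (a in 1:3) {
    inc <- tapply(A / 3, tri[, a], sum)
    M[as.integer(names(inc))] <- M[as.integer(names(inc))] + inc
  }
  list(M = M, K = Matrix::forceSymmetric((K + Matrix::t(K)) / 2))
}

#' Stimulation protocol
#'
#' @param n_beats stabilization beats paced at the SAN patch (default 2; the
#'   reference protocol uses 20).
#' @param BCL basic cycle length (ms).
#' @param focus id of the ectopic focus (or `"SAN"` for a sinus beat).
#' @param pulse_ms,amplitude ectopic square pulse duration (ms) and amplitude
#'   (pA/pF).
#' @param record_window recording window after the ectopic pulse (ms).
#' @param output_step output sampling step (ms).
#' @return list of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(n_beats = 2, BCL = 500, focus = "SAN",
                              pulse_ms = 2, amplitude = 28,
                              record_window = 350, output_step = 1) {
  if (pulse_ms <= 0 || amplitude < 0) parameter_error("invalid stimulus")
  structure(list(n_beats = n_beats, BCL = BCL, focus = focus,
                 pulse_ms = pulse_ms, amplitude = amplitude,
                 record_window = record_window, output_step = output_step),
            class = "stimulus_protocol")
}

#' Solve the monodomain equation for one ectopic beat
#'
#' Paces the SAN patch for `protocol$n_beats` stabilization beats, then
#' delivers the ectopic square pulse on the focus patch and records the
#' transmembrane potential over the record window.
#'
#' @param mesh annotated `atrial_mesh`.
#' @param cond `conductivity_field`.
#' @param model `membrane_model`.
#' @param protocol `stimulus_protocol`.
#' @param catalog `foci_catalog` resolving focus ids to node patches.
#' @param dt time step (ms), default 0.05; checked against the explicit
#'   membrane stability limit.
#' @return object of class `voltage_trace`: `V` (nodes x times, mV), `times`
#'   (ms), `stim_time` (ms), `no_capture` flag.
#' @export
solve_monodomain <- function(mesh, cond, model, protocol, catalog,
                             dt = 0.05) {
  if (dt > 0.25 * model$tau_in)
    parameter_error(sprintf("dt = %g exceeds the membrane stability limit %g ms",
                            dt, 0.25 * model$tau_in))
  sys <- assemble_monodomain(mesh, cond)
  n <- nrow(mesh$nodes)
  Amat <- Matrix::Diagonal(x = sys$M) + dt * sys$K / model$C_m
  ch <- Matrix::Cholesky(Amat, LDL = FALSE)
  Mv <- sys$M

  node_reg <- node_regions(mesh)
  tcl <- vapply(node_reg, function(r) ms_tau_close(model, r), numeric(1))

  san_patch <- focus_patch(catalog, "SAN")
  ect_patch <- if (identical(protocol$focus, "SAN")) san_patch
               else focus_patch(catalog, protocol$focus)
  amp_v <- protocol$amplitude / (model$V_peak - model$V_rest)

  t_stim <- protocol$n_beats * protocol$BCL
  t_end <- t_stim + protocol$record_window
  nt <- ceiling(t_end / dt)
  out_times <- seq(t_stim, t_end, by = protocol$output_step)
  Vout <- matrix(NA_real_, n, length(out_times))
  out_i <- 1

  v <- numeric(n); w <- rep(1, n)
  for (i in seq_len(nt)) {
    t <- (i - 1) * dt
    stim <- numeric(n)
    if (t < t_stim) {
      phase <- t %% protocol$BCL
      if (phase < protocol$pulse_ms) stim[san_patch] <- amp_v
    } else if (t - t_stim < protocol$pulse_ms) {
      stim[ect_patch] <- amp_v
    }
    dv <- w * v^2 * (1 - v) / model$tau_in - v / model$tau_out + stim
    open <- v < model$v_gate
    w <- w + dt * ifelse(open, (1 - w) / model$tau_open, -w / tcl)
    w <- pmin(1, pmax(0, w))
    v <- v + dt * dv
    ## implicit diffusion
    v <- as.numeric(Matrix::solve(ch, Mv * v, system = "A"))
    if (max(abs(v)) > 5) bspim_error("monodomain instability (|V| > 500 mV)",
                                     "bspim_timestep_error")
    while (out_i <= length(out_times) && t + dt >= out_times[out_i] - 1e-9) {
      Vout[, out_i] <- v
      out_i <- out_i + 1
    }
  }
  V <- model$V_rest + (model$V_peak - model$V_rest) * Vout
  outside <- if (length(ect_patch)) V[-ect_patch, , drop = FALSE] else V
  no_capture <- nrow(outside) > 0 && max(outside) < model$V_rest + 10
  structure(list(V = V, times = out_times, stim_time = t_stim,
                 no_capture = no_capture, model = model),
            class = "voltage_trace")
}

## Majority region per node.
node_regions <- function(mesh) {
  tri <- mesh$triangles
  reg3 <- rep(mesh$region, 3)
  nd3 <- c(tri[, 1], tri[, 2], tri[, 3])
  sp <- split(reg3, nd3)
  res <- character(nrow(mesh$nodes))
  res[as.integer(names(sp))] <- vapply(sp, function(r) names(which.max(table(r))), character(1))
  res
}

focus_patch <- function(catalog, id) {
  i <- match(id, catalog$id)
  if (is.na(i)) parameter_error(paste("unknown focus id", id))
  attr(catalog, "patches")[[i]]
}

#' Local activation times from a voltage trace
#'
#' First upward crossing of the threshold after the stimulus time, linearly
#' interpolated between output samples.
#'
#' @param trace a `voltage_trace`.
#' @param threshold crossing threshold (mV); must lie above the resting
#'   potential.  Default -40 mV.
#' @param max_unreached tolerated fraction of unreached nodes before an error
#'   is raised (default 0.01).
#' @return object of class `lat_map`: `lat` (ms relative to `stim_time`,
#'   `Inf` for unreached nodes), `threshold`, `stim_time`.
#' @export
compute_lat <- function(trace, threshold = -40, max_unreached = 0.01) {
  if (threshold <= trace$model$V_rest %||% -80)
    parameter_error("threshold at or below the resting potential")
  V <- trace$V
  sel <- trace$times >= trace$stim_time - 1e-9
  V <- V[, sel, drop = FALSE]
  tt <- trace$times[sel] - trace$stim_time
  above <- V >= threshold
  first <- apply(above, 1, function(a) {
    i <- which(a & !c(FALSE, a[-length(a)]))
    if (length(i)) i[1] else NA_integer_
  })
  lat <- rep(Inf, nrow(V))
  ok <- !is.na(first) & first > 1
  i1 <- first[ok]
  v0 <- V[cbind(which(ok), i1 - 1)]
  v1 <- V[cbind(which(ok), i1)]
  frac <- (threshold - v0) / (v1 - v0)
  lat[ok] <- tt[i1 - 1] + frac * (tt[i1] - tt[i1 - 1])
  ## nodes already above threshold at the first sample activated at ~0
  ok0 <- !is.na(first) & first == 1
  lat[ok0] <- tt[1]
  if (mean(!is.finite(lat)) > max_unreached)
    bspim_error(sprintf("%.1f%% of nodes never crossed threshold",
                        100 * mean(!is.finite(lat))), "bspim_capture_error")
  structure(list(lat = lat, threshold = threshold, stim_time = trace$stim_time),
            class = "lat_map")
}
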