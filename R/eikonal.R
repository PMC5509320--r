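## Anisotropic eikonal solver on the triangulated surface (fast surrogate
## for the monodomain model).  Per-triangle wavefront speeds derive from the
## conduction tensor through v = v_ref * sqrt(sigma / sigma_ref), with the
## reference speed calibrated once against the monodomain solver on a planar
## strip.  The solver performs vectorized Jacobi sweeps of the standard
## two-point triangle update (Fast-Iterative-Method contract); units mm, ms.

#' Default eikonal speed calibration
#'
#' One-off planar-strip calibration of the reference conduction velocity: a
#' monodomain cable with sigma_ref = 0.003 S/(cm pF) and the default
#' membrane model propagates at v_ref mm/ms.  Recompute with
#' [calibrate_eikonal()].
#' @return list `sigma_ref`, `v_ref` (mm/ms).
#' @export
default_eikonal_calibration <- function() {
  list(sigma_ref = 0.003, v_ref = 0.5835)
}

#' Recalibrate the eikonal reference speed against the monodomain solver
#'
#' Runs the monodomain model on a thin planar strip at `sigma_ref` and
#' regresses local activation time on distance.
#'
#' @param model a [membrane_model()].
#' @param sigma_ref reference diffusivity (S/(cm pF)).
#' @param dx strip resolution (mm).
#' @param length_mm strip length (mm).
#' @return list `sigma_ref`, `v_ref` (mm/ms).
#' @export
calibrate_eikonal <- function(model = membrane_model(), sigma_ref = 0.003,
                              dx = 0.2, length_mm = 20) {
  strip <- strip_mesh(length_mm = length_mm, width_mm = 1, dx = dx)
  tab <- data.frame(region = "RA_WALL", sigma_l = sigma_ref, sigma_t = sigma_ref,
                    sigma_i_l = 2 * sigma_ref, sigma_i_t = 2 * sigma_ref)
  cond <- build_conductivity(strip, tab)
  cv <- strip_conduction_velocity(strip, cond, model)
  list(sigma_ref = sigma_ref, v_ref = cv)
}

#' Planar strip mesh for cable experiments
#'
#' Structured triangulated rectangle in the z = 0 plane, fibers along +x,
#' uniform region label; stimulation patch = the left edge.
#'
#' @param length_mm,width_mm,dx geometry (mm).
#' @param region region label applied to all triangles.
#' @return an `atrial_mesh`-compatible object with attribute `left_edge`
#'   (node indices of the x = 0 column).
#' @export
strip_mesh <- function(length_mm = 20, width_mm = 1, dx = 0.2,
                       region = "RA_WALL") {
  nx <- round(length_mm / dx) + 1
  ny <- max(2, round(width_mm / dx) + 1)
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dx
  nodes <- cbind(rep(xs, each = ny), rep(ys, nx), 0)
  id <- function(i, j) (i - 1) * ny + j  # i along x, j along y
  ## union-jack pattern: a center node per cell, four triangles, so the
  ## two-point update sees characteristics in eight directions
  ncorner <- nrow(nodes)
  ci <- rep(seq_len(nx - 1), each = ny - 1)
  cj <- rep(seq_len(ny - 1), nx - 1)
  centers <- cbind(xs[ci] + dx / 2, ys[cj] + dx / 2, 0)
  nodes <- rbind(nodes, centers)
  cid <- ncorner + seq_len(length(ci))
  a <- id(ci, cj); b <- id(ci + 1, cj); cc <- id(ci + 1, cj + 1); d <- id(ci, cj + 1)
  tris <- rbind(cbind(a, b, cid), cbind(b, cc, cid),
                cbind(cc, d, cid), cbind(d, a, cid))
  nt <- nrow(tris)
  mesh <- structure(list(
    nodes = nodes, triangles = tris,
    region = rep(region, nt),
    conn_id = rep(NA_character_, nt),
    fiber = matrix(rep(c(1, 0, 0), each = nt), nt, 3),
    atrium = rep("RA", nrow(nodes)),
    orifices = list(),
    meta = list(params = NULL)
  ), class = "atrial_mesh")
  attr(mesh, "left_edge") <- which(nodes[, 1] <= 1.0 + 1e-9)
  mesh
}

## Monodomain conduction velocity on a strip (mm/ms) by LAT regression over
## the central portion of the cable.
strip_conduction_velocity <- function(strip, cond, model, dt = 0.05) {
  n <- nrow(strip$nodes)
  patches <- list(attr(strip, "left_edge"))
  cat_df <- data.frame(id = "SAN", center_node = patches[[1]][1], radius = 1,
                       atrium = "RA", region = strip$region[1])
  attr(cat_df, "patches") <- patches
  class(cat_df) <- c("foci_catalog", "data.frame")
  proto <- stimulus_protocol(n_beats = 0, focus = "SAN", record_window = 120,
                             output_step = 0.5)
  tr <- solve_monodomain(strip, cond, model, proto, cat_df, dt = dt)
  lm_ <- compute_lat(tr)
  x <- strip$nodes[, 1]
  sel <- x > 0.25 * max(x) & x < 0.75 * max(x) & is.finite(lm_$lat)
  fit <- stats::lm(lm_$lat[sel] ~ x[sel])
  1 / unname(stats::coef(fit)[2])
}

## Precompute the per-(vertex, opposite-edge) update constants for a mesh +
## conductivity; reusable across focus patches.
eikonal_setup <- function(mesh, cond, calib = default_eikonal_calibration()) {
  tri <- mesh$triangles
  p <- mesh$nodes
  f <- cond$fiber
  geo <- triangle_normals_areas(p, tri)
  tdir <- rowcross(geo$normals, f)
  vl <- calib$v_ref * sqrt(cond$sigma_l / calib$sigma_ref)
  vt <- calib$v_ref * sqrt(cond$sigma_t / calib$sigma_ref)
  ## inverse speed-squared metric restricted to the triangle plane:
  ## time(d) = sqrt(d' Minv d), Minv = f f'/vl^2 + t t'/vt^2
  vp <- c(tri[, 1], tri[, 2], tri[, 3])
  va <- c(tri[, 2], tri[, 3], tri[, 1])
  vb <- c(tri[, 3], tri[, 1], tri[, 2])
  tid <- rep(seq_len(nrow(tri)), 3)
  eab <- p[va, , drop = FALSE] - p[vb, , drop = FALSE]
  epb <- p[vp, , drop = FALSE] - p[vb, , drop = FALSE]
  fT <- f[tid, , drop = FALSE]; tT <- tdir[tid, , drop = FALSE]
  vlT <- vl[tid]; vtT <- vt[tid]
  quad <- function(u, v) {
    rowSums(fT * u) * rowSums(fT * v) / vlT^2 +
      rowSums(tT * u) * rowSums(tT * v) / vtT^2
  }
  c2 <- quad(eab, eab)
  c1 <- quad(eab, epb)
  c0 <- quad(epb, epb)
  n <- nrow(p)
  ## index matrix: rows grouped by apex vertex
  ord <- order(vp)
  deg <- tabulate(vp, nbins = n)
  K <- max(deg)
  idx <- matrix(NA_integer_, n, K)
  pos <- c(0, cumsum(deg))
  idx_fill <- cbind(vp[ord], sequence(deg[deg > 0]))
  idx[idx_fill] <- ord
  list(va = va, vb = vb, c2 = c2, c1 = c1, c0 = c0, idx = idx, n = n)
}

## Triangle update, vectorized over all rows: candidate arrival time at the
## apex from arrival times Ta, Tb on the opposite edge.
eikonal_update <- function(su, Ta, Tb) {
  BIG <- 1e15   # finite sentinel for "not yet reached" (0 * Inf = NaN)
  Ta <- pmin(Ta, BIG); Tb <- pmin(Tb, BIG)
  u <- Ta - Tb
  c2 <- su$c2; c1 <- su$c1; c0 <- su$c0
  gval <- function(l) l * Ta + (1 - l) * Tb + sqrt(pmax(c2 * l^2 - 2 * c1 * l + c0, 0))
  cand <- pmin(gval(0), gval(1))
  den <- c2 - u^2                      # causality requires den > 0
  rad <- den * (c0 * c2 - c1^2)        # >= 0 by Cauchy-Schwarz when den > 0
  okd <- which(den > 1e-300 & rad >= 0 & is.finite(u))
  if (length(okd)) {
    s <- sqrt(rad[okd]) / c2[okd]
    base <- c1[okd] / c2[okd]
    for (lam in list(base + u[okd] * s / den[okd], base - u[okd] * s / den[okd])) {
      ok <- lam > 0 & lam < 1
      if (any(ok)) {
        i <- okd[ok]
        li <- lam[ok]
        g <- li * Ta[i] + (1 - li) * Tb[i] +
          sqrt(pmax(c2[i] * li^2 - 2 * c1[i] * li + c0[i], 0))
        cand[i] <- pmin(cand[i], g)
      }
    }
  }
  cand
}

#' Solve the anisotropic eikonal equation from a focus patch
#'
#' Arrival time 0 on the patch; elsewhere the anisotropic distance induced by
#' the conduction-derived speed tensor, computed by vectorized fixed-point
#' sweeps of the two-point triangle update until convergence.
#'
#' @param mesh annotated `atrial_mesh`.
#' @param cond `conductivity_field`.
#' @param focus_patch node indices with arrival time 0.
#' @param calib speed calibration ([default_eikonal_calibration()]).
#' @param setup optional precomputed [eikonal_setup()] (reused across foci).
#' @param tol convergence tolerance (ms).
#' @return a `lat_map` (threshold tag `"eikonal"`); unreached nodes `Inf`.
#' @export
solve_eikonal <- function(mesh, cond, focus_patch,
                          calib = default_eikonal_calibration(),
                          setup = NULL, tol = 1e-9, exact_init_factor = 3) {
  su <- setup %||% eikonal_setup(mesh, cond, calib)
  T <- rep(Inf, su$n)
  T[focus_patch] <- 0
  ## exact local initialization around the source (standard treatment of the
  ## point-source singularity): nodes within a few edge lengths get the
  ## analytic anisotropic distance under their local metric
  if (exact_init_factor > 0) {
    tri <- mesh$triangles
    el <- rownorms(mesh$nodes[tri[, 2], , drop = FALSE] -
                   mesh$nodes[tri[, 1], , drop = FALSE])
    r_init <- exact_init_factor * mean(el)
    P <- mesh$nodes[focus_patch, , drop = FALSE]
    d2 <- outer(rowSums(mesh$nodes^2), rowSums(P^2), `+`) -
      2 * mesh$nodes %*% t(P)
    near <- which(sqrt(pmax(apply(d2, 1, min), 0)) <= r_init)
    near <- setdiff(near, focus_patch)
    if (length(near)) {
      geo <- triangle_normals_areas(mesh$nodes, tri)
      f <- cond$fiber; tdir <- rowcross(geo$normals, f)
      vl <- calib$v_ref * sqrt(cond$sigma_l / calib$sigma_ref)
      vt <- calib$v_ref * sqrt(cond$sigma_t / calib$sigma_ref)
      inc <- split(rep(seq_len(nrow(tri)), 3), as.vector(tri))
      for (nd in near) {
        best <- Inf
        for (e in inc[[as.character(nd)]]) {
          dv <- sweep(P, 2, mesh$nodes[nd, ], `-`)
          tm <- sqrt((dv %*% f[e, ])^2 / vl[e]^2 + (dv %*% tdir[e, ])^2 / vt[e]^2 +
                     ((dv %*% geo$normals[e, ])^2) / vt[e]^2)
          best <- min(best, min(tm))
        }
        T[nd] <- best
      }
    }
  }
  idx <- su$idx
  K <- ncol(idx)
  repeat {
    Ta <- T[su$va]; Tb <- T[su$vb]
    cand <- eikonal_update(su, Ta, Tb)
    cand[!is.finite(cand)] <- Inf
    Tnew <- T
    for (k in seq_len(K)) {
      col <- idx[, k]
      has <- !is.na(col)
      Tnew[has] <- pmin(Tnew[has], cand[col[has]])
    }
    delta <- abs(Tnew - T)
    delta[!is.finite(delta)] <- Inf
    changed <- is.finite(Tnew) != is.finite(T)
    if (!any(changed) && max(delta[is.finite(Tnew)], 0) <= tol) {
      T <- Tnew
      break
    }
    T <- Tnew
  }
  T[T > 1e14] <- Inf
  structure(list(lat = T, threshold = "eikonal", stim_time = 0),
            class = "lat_map")
}

#' Reconstruct a voltage trace from activation times (fast mode)
#'
#' Every node plays its regional action-potential template shifted by its
#' activation time: V(x, t) = template_region(x)(t - lat(x)).
#'
#' @param latmap a `lat_map` with finite activation everywhere.
#' @param mesh the mesh (for node regions).
#' @param model a [membrane_model()].
#' @param times output sample times (ms, relative to stimulus onset).
#' @return a `voltage_trace`.
#' @export
lat_to_voltage <- function(latmap, mesh, model, times = seq(0, 350, by = 1)) {
  if (any(!is.finite(latmap$lat)))
    validation_error("lat map contains unreached nodes")
  nreg <- node_regions(mesh)
  n <- length(latmap$lat)
  V <- matrix(model$V_rest, n, length(times))
  for (rg in unique(nreg)) {
    nd <- which(nreg == rg)
    ## quarter-ms template sampling keeps the reconstructed upstroke sharp
    ## enough for compute_lat() to round-trip within one output step
    tpl <- ap_template(model, rg, dt_out = 0.25)
    tt <- outer(-latmap$lat[nd], times, `+`)  # t - lat
    dtt <- tpl$t[2] - tpl$t[1]
    k <- floor(tt / dtt)
    frac <- tt / dtt - k
    inb <- k >= 0 & k <= length(tpl$t) - 2
    kc <- pmax(pmin(k, length(tpl$t) - 2), 0)
    vlow <- ifelse(inb, tpl$V[kc + 1], model$V_rest)
    vhig <- ifelse(inb, tpl$V[kc + 2], model$V_rest)
    V[nd, ] <- vlow + frac * (vhig - vlow)
  }
  structure(list(V = V, times = times, stim_time = 0, no_capture = FALSE,
                 model = model),
            class = "voltage_trace")
}
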