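## Forward projection of transmembrane voltage to body-surface potentials:
## per-triangle equivalent current dipoles p = -(D_i grad V) * area feed an
## infinite homogeneous volume conductor,
##   Ve(r) = sum_e p_e . (r - c_e) / (4 pi sigma_torso |r - c_e|^3),
## evaluated at the lead positions.  Distances in cm, potentials nominal mV.

#' Per-triangle equivalent dipoles at one instant
#'
#' The gradient of V is linear-interpolated over each triangle; the dipole is
#' the intracellular-conductivity-weighted negative gradient times the
#' triangle area.
#'
#' @param v_nodes voltage at the nodes (mV) at one instant.
#' @param mesh annotated `atrial_mesh`.
#' @param cond `conductivity_field`.
#' @return object of class `dipole_field`: `p` (nt x 3, dipole moments),
#'   `centroids` (nt x 3, mm).
#' @export
element_dipoles <- function(v_nodes, mesh, cond) {
  op <- gradient_operator(mesh, cond)
  p <- matrix(as.numeric(op$P %*% v_nodes), ncol = 3)
  structure(list(p = p, centroids = op$centroids), class = "dipole_field")
}

## Sparse operator taking nodal V to stacked dipole components (3 nt x n).
## Cached on the mesh environment by caller where needed.
gradient_operator <- function(mesh, cond) {
  tri <- mesh$triangles
  p <- mesh$nodes / 10  # cm
  geo <- triangle_normals_areas(p, tri)
  A <- geo$areas
  n <- geo$normals
  p1 <- p[tri[, 1], , drop = FALSE]
  p2 <- p[tri[, 2], , drop = FALSE]
  p3 <- p[tri[, 3], , drop = FALSE]
  g1 <- rowcross(n, p3 - p2) / (2 * A)
  g2 <- rowcross(n, p1 - p3) / (2 * A)
  g3 <- rowcross(n, p2 - p1) / (2 * A)
  f <- cond$fiber
  tdir <- rowcross(n, f)
  apply_Di <- function(g) {
    f * (cond$sigma_i_l * rowSums(f * g)) + tdir * (cond$sigma_i_t * rowSums(tdir * g))
  }
  D1 <- apply_Di(g1); D2 <- apply_Di(g2); D3 <- apply_Di(g3)
  nt <- nrow(tri)
  ## rows: dipole components (x block, y block, z block); columns: nodes
  ii <- c(); jj <- c(); xx <- c()
  for (k in 1:3) {
    Dk <- list(D1, D2, D3)[[k]]
    for (c_ in 1:3) {
      ii <- c(ii, (c_ - 1) * nt + seq_len(nt))
      jj <- c(jj, tri[, k])
      xx <- c(xx, -A * Dk[, c_])
    }
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(3 * nt, nrow(p)))
  list(P = P, centroids = triangle_centroids(mesh$nodes, tri))
}

#' Project a dipole field to lead potentials (one instant)
#'
#' Infinite homogeneous volume conductor: superposition of current-dipole
#' far fields.
#'
#' @param dipoles a `dipole_field`.
#' @param leads a `lead_set`.
#' @param torso_sigma torso conductivity (S/cm), default 0.002 (0.2 S/m).
#' @return numeric vector of per-lead potentials.
#' @export
project_to_leads <- function(dipoles, leads, torso_sigma = 0.002) {
  Tm <- transfer_matrix(dipoles$centroids, leads, torso_sigma)
  as.numeric(Tm %*% as.numeric(dipoles$p))
}

## Dense lead x (3 nt) transfer matrix; centroids and leads in mm -> cm.
transfer_matrix <- function(centroids, leads, torso_sigma) {
  L <- lead_positions(leads) / 10
  C <- centroids / 10
  nl <- nrow(L); nt <- nrow(C)
  dx <- outer(L[, 1], C[, 1], `-`)
  dy <- outer(L[, 2], C[, 2], `-`)
  dz <- outer(L[, 3], C[, 3], `-`)
  r2 <- dx^2 + dy^2 + dz^2
  if (any(r2 < 1e-12)) bspim_error("lead coincides with a source centroid",
                                   "bspim_singularity_error")
  w <- 1 / (4 * pi * torso_sigma * r2^1.5)
  cbind(dx * w, dy * w, dz * w)
}

#' Assemble the body-surface potential map for a voltage trace
#'
#' @param trace a `voltage_trace`.
#' @param mesh,cond geometry and conductivities.
#' @param leads a `lead_set`.
#' @param torso_sigma torso conductivity (S/cm).
#' @param reference `"mean"` (zero-mean over leads at every instant, default)
#'   or `"none"` (raw infinite-medium values).
#' @return object of class `bspm`: `Ve` (lead x time, mV), `times`, `labels`,
#'   `reference`, `torso_sigma`.
#' @export
compute_bspm <- function(trace, mesh, cond, leads, torso_sigma = 0.002,
                         reference = c("mean", "none")) {
  reference <- match.arg(reference)
  op <- gradient_operator(mesh, cond)
  Tm <- transfer_matrix(op$centroids, leads, torso_sigma)
  B <- as.matrix(Tm %*% op$P)        # lead x node transfer
  Ve <- B %*% trace$V
  if (reference == "mean") Ve <- sweep(Ve, 2, colMeans(Ve))
  structure(list(Ve = Ve, times = trace$times, labels = leads$label,
                 reference = reference, torso_sigma = torso_sigma,
                 stim_time = trace$stim_time),
            class = "bspm")
}

#' Precompute the lead transfer operator for repeated forward runs
#'
#' @inheritParams compute_bspm
#' @return dense matrix (leads x nodes) mapping nodal voltage to lead
#'   potentials.
#' @export
lead_transfer_operator <- function(mesh, cond, leads, torso_sigma = 0.002) {
  op <- gradient_operator(mesh, cond)
  Tm <- transfer_matrix(op$centroids, leads, torso_sigma)
  as.matrix(Tm %*% op$P)
}

#' @export
print.bspm <- function(x, ...) {
  cat(sprintf("<bspm> %d leads x %d samples, reference=%s\n",
              nrow(x$Ve), ncol(x$Ve), x$reference))
  invisible(x)
}
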