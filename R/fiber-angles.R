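## Discrete smoothness measure for per-triangle fiber fields: fibers of two
## edge-adjacent triangles are compared after hinge-unfolding (parallel
## transport across the shared edge), so a surface crease does not by itself
## count as fiber discontinuity.  Fibers are axes: the acute angle is used.

#' Adjacent-triangle fiber angles
#'
#' @param mesh an annotated `atrial_mesh`.
#' @return data.frame with triangle pair indices `t1`, `t2`, logical
#'   `same_region` and `angle_deg` (hinge-unfolded acute angle).
#' @export
fiber_adjacency_angles <- function(mesh) {
  tri <- mesh$triangles
  geo <- triangle_normals_areas(mesh$nodes, tri)
  n <- geo$normals
  de <- directed_edges(tri)
  key <- undirected_key(de)
  tid <- rep(seq_len(nrow(tri)), 3)
  sp <- split(tid, key)
  prs <- do.call(rbind, sp[lengths(sp) == 2])
  f1 <- mesh$fiber[prs[, 1], , drop = FALSE]
  f2 <- mesh$fiber[prs[, 2], , drop = FALSE]
  n1 <- n[prs[, 1], , drop = FALSE]
  n2 <- n[prs[, 2], , drop = FALSE]
  ## rotate f1 about n1 x n2 so that plane 1 lands on plane 2
  ax <- rowcross(n1, n2)
  s <- rownorms(ax)
  c_ <- rowSums(n1 * n2)
  f1r <- f1
  nz <- s > 1e-12
  if (any(nz)) {
    a <- ax[nz, , drop = FALSE] / s[nz]
    v <- f1[nz, , drop = FALSE]
    cth <- pmin(1, pmax(-1, c_[nz]))
    sth <- s[nz] * sign(1)  # sin(theta) with theta in [0, pi)
    adotv <- rowSums(a * v)
    f1r[nz, ] <- v * cth + rowcross(a, v) * sth + a * adotv * (1 - cth)
  }
  dotv <- abs(rowSums(f1r * f2))
  nrm <- rownorms(f1r) * rownorms(f2)
  ang <- acos(pmin(1, dotv / pmax(nrm, 1e-12))) * 180 / pi
  data.frame(t1 = prs[, 1], t2 = prs[, 2],
             same_region = mesh$region[prs[, 1]] == mesh$region[prs[, 2]],
             angle_deg = ang)
}
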