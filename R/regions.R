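## Regional annotation: anatomical region labels, rule-based fiber fields and
## the anisotropic conduction tensor field.

#' Atrial region labels used by the synthetic model
#'
#' @return character vector of the 21 region codes.
#' @export
atrial_region_labels <- function() {
  c("SAN", "CT", "BB_R", "BB_L", "RA_WALL", "RAA", "SVC", "IVC", "TV_RING",
    "FO", "RA_SEPTUM", "LA_WALL", "LAA", "PV_LSPV", "PV_LIPV", "PV_RSPV",
    "PV_RIPV", "MV_RING", "LA_POST", "CS_SLEEVE", "BRIDGE_PROX", "BRIDGE_DIST")
}

## Outward normal of the ellipsoid at the surface point in direction `dir`.
ellipsoid_normal_at <- function(chamber, dir) {
  p <- ellipsoid_anchor(chamber, dir) - chamber$center
  normalize(p / chamber$semi^2)
}

## Angular coordinates of triangle centroids in a chamber's normalized frame.
chamber_units <- function(cen, chamber) {
  d <- sweep(sweep(cen, 2, chamber$center), 2, chamber$semi, `/`)
  d / rownorms(d)
}

unit_dir <- function(chamber, dir) normalize(normalize(dir) / chamber$semi)

#' Assign region labels and fiber orientations
#'
#' Labels every chamber triangle with an anatomical region (connection tubes
#' are labelled at build time) and attaches a per-triangle in-plane unit fiber
#' vector.  The default rule set emulates the qualitative fiber architecture
#' of the atria: circumferential wall fibers around the caval (RA) and
#' mitral--left-superior-pulmonary-vein (LA) axes, crista terminalis and
#' Bachmann-bundle fibers along the bundle long axis, circumferential fibers
#' around the valve rings and venous sleeves, and axial fibers in the
#' interatrial tubes.
#'
#' @param mesh an `atrial_mesh` from [build_biatrial_mesh()].
#' @param params the [geometry_params()] used to build it.  Set
#'   `params$fiber_rule = "latitudinal"` (with optional `params$fiber_axis`)
#'   to bypass the regional rules and use one global rotational field (used
#'   for testing on simple closed surfaces).
#' @return the mesh with `region` fully populated and `fiber` set.
#' @export
assign_fibers_and_regions <- function(mesh, params = mesh$meta$params) {
  tri <- mesh$triangles
  geo <- triangle_normals_areas(mesh$nodes, tri)
  n <- geo$normals
  cen <- triangle_centroids(mesh$nodes, tri)

  if (identical(params$fiber_rule, "latitudinal")) {
    axis <- params$fiber_axis %||% c(0, 0, 1)
    f <- rowcross(matrix(axis, nrow(tri), 3, byrow = TRUE), n)
    mesh$fiber <- f / rownorms(f)
    mesh$region <- ifelse(is.na(mesh$region), "RA_WALL", mesh$region)
    return(mesh)
  }

  region <- mesh$region
  atr_tri <- mesh$atrium[tri[, 1]]
  ra <- params$ra; la <- params$la

  ## --- region rules -------------------------------------------------------
  u_ra <- chamber_units(cen, ra)
  u_la <- chamber_units(cen, la)
  ang_to <- function(u, chamber, dir, radius_mm) {
    ua <- unit_dir(chamber, dir)
    rl <- vnorm(ellipsoid_anchor(chamber, dir) - chamber$center)
    acos(pmin(1, pmax(-1, u %*% ua))) <= radius_mm / rl
  }
  ors <- params$orifices
  conns <- params$connections
  is_ra <- is.na(region) & atr_tri == "RA"
  is_la <- is.na(region) & atr_tri == "LA"

  ## RA, in priority order
  san_dir <- c(0.45, 0.25, 0.80)
  raa_dir <- c(-0.45, -0.70, 0.55)
  set_if <- function(region, mask, label) {
    region[mask & is.na(region)] <- label
    region
  }
  region <- set_if(region, is_ra & ang_to(u_ra, ra, san_dir, 4.5), "SAN")
  region <- set_if(region, is_ra & ang_to(u_ra, ra, ors$SVC$dir, ors$SVC$radius + 4), "SVC")
  region <- set_if(region, is_ra & ang_to(u_ra, ra, ors$IVC$dir, ors$IVC$radius + 4), "IVC")
  region <- set_if(region, is_ra & ang_to(u_ra, ra, ors$TV$dir, ors$TV$radius + 5), "TV_RING")
  ## crista terminalis: posterolateral meridian band between the cavae
  az <- atan2(u_ra[, 2], u_ra[, 1])
  az_ct <- atan2(0.55, -0.55)
  dphi <- abs(((az - az_ct + pi) %% (2 * pi)) - pi)
  region <- set_if(region, is_ra & dphi <= 0.26 & abs(u_ra[, 3]) <= 0.72, "CT")
  region <- set_if(region, is_ra & ang_to(u_ra, ra, raa_dir, 6), "RAA")
  cs_mask <- rep(FALSE, nrow(tri))
  for (nm in grep("^CS_BRIDGE_", names(conns), value = TRUE))
    cs_mask <- cs_mask | ang_to(u_ra, ra, conns[[nm]]$ra_dir, 6)
  region <- set_if(region, is_ra & cs_mask, "CS_SLEEVE")
  region <- set_if(region, is_ra & u_ra[, 1] >= 0.60, "RA_SEPTUM")
  region <- set_if(region, is_ra, "RA_WALL")

  ## LA, in priority order
  laa_dir <- c(0.50, -0.60, 0.62)
  pvs <- intersect(c("LSPV", "LIPV", "RSPV", "RIPV"), names(ors))
  for (pv in pvs)
    region <- set_if(region, is_la & ang_to(u_la, la, ors[[pv]]$dir, ors[[pv]]$radius + 3),
                     paste0("PV_", pv))
  region <- set_if(region, is_la & ang_to(u_la, la, ors$MV$dir, ors$MV$radius + 5), "MV_RING")
  region <- set_if(region, is_la & ang_to(u_la, la, laa_dir, 6), "LAA")
  region <- set_if(region, is_la & u_la[, 2] >= 0.45, "LA_POST")
  region <- set_if(region, is_la, "LA_WALL")

  if (anyNA(region)) bspim_error("unlabeled triangles remain after annotation",
                                 "bspim_annotation_error")

  ## --- fiber rules --------------------------------------------------------
  rot_field <- function(axis) {
    f <- rowcross(matrix(axis, nrow(tri), 3, byrow = TRUE), n)
    nr <- rownorms(f)
    bad <- nr < 1e-8
    f[bad, ] <- NA
    f / pmax(nr, 1e-8)
  }
  proj_field <- function(v) {
    vm <- matrix(v, nrow(tri), 3, byrow = TRUE)
    f <- vm - n * as.numeric(rowSums(vm * n))
    nr <- rownorms(f)
    f[nr < 1e-8, ] <- NA
    f / pmax(nr, 1e-8)
  }
  a_ra <- ellipsoid_normal_at(ra, ors$SVC$dir)
  a_la <- ellipsoid_normal_at(la, ors$MV$dir)
  a_tv <- ellipsoid_normal_at(ra, ors$TV$dir)
  fib <- matrix(NA_real_, nrow(tri), 3)
  put <- function(fib, mask, field) { fib[mask, ] <- field[mask, ]; fib }

  f_wall_ra <- rot_field(a_ra)
  fib <- put(fib, region %in% c("RA_WALL", "RA_SEPTUM", "SVC", "IVC"), f_wall_ra)
  fib <- put(fib, region %in% c("CT", "SAN"), proj_field(a_ra))
  fib <- put(fib, region == "TV_RING", rot_field(a_tv))
  t_raa <- normalize(pracma_cross(a_ra, normalize(raa_dir)))
  fib <- put(fib, region == "RAA", proj_field(t_raa))
  brs <- grep("^CS_BRIDGE_", names(conns), value = TRUE)
  cs_tan <- if (length(brs) >= 2) {
    normalize(ellipsoid_anchor(ra, conns[[brs[length(brs)]]]$ra_dir) -
              ellipsoid_anchor(ra, conns[[brs[1]]]$ra_dir))
  } else normalize(c(-0.2, 0.9, 0.4))
  fib <- put(fib, region == "CS_SLEEVE", proj_field(cs_tan))

  f_wall_la <- rot_field(a_la)
  fib <- put(fib, region %in% c("LA_WALL", "LA_POST", "MV_RING"), f_wall_la)
  for (pv in pvs) {
    a_pv <- ellipsoid_normal_at(la, ors[[pv]]$dir)
    fib <- put(fib, region == paste0("PV_", pv), rot_field(a_pv))
  }
  t_laa <- normalize(pracma_cross(a_la, normalize(laa_dir)))
  fib <- put(fib, region == "LAA", proj_field(t_laa))

  ## connection tubes: fibers along the bundle long axis.  Near the chamber
  ## junctions the triangle plane can be nearly perpendicular to the tube
  ## axis, so the in-plane direction towards the far end of the tube is used
  ## (which reduces to the axis projection mid-tube).
  if (!is.null(mesh$conn_id)) {
    for (nm in names(mesh$meta$conn_axes)) {
      mask <- which(!is.na(mesh$conn_id) & mesh$conn_id == nm)
      if (!length(mask)) next
      ends <- mesh$meta$conn_axes[[nm]]$ends
      axv <- ends[2, ] - ends[1, ]
      fr <- as.numeric(sweep(cen[mask, , drop = FALSE], 2, ends[1, ]) %*% axv) / sum(axv^2)
      towards <- sweep(-cen[mask, , drop = FALSE], 2, ends[2, ], `+`)
      from <- sweep(cen[mask, , drop = FALSE], 2, ends[1, ])
      towards[fr > 0.5, ] <- from[fr > 0.5, , drop = FALSE]
      nm_n <- n[mask, , drop = FALSE]
      f <- towards - nm_n * as.numeric(rowSums(towards * nm_n))
      nr <- rownorms(f)
      ok <- nr > 1e-8
      fib[mask[ok], ] <- f[ok, , drop = FALSE] / nr[ok]
      fib <- smooth_fiber_patch(mesh, fib, mask, n, iters = 60)
    }
  }

  ## degenerate projections: fall back to first edge direction
  bad <- which(is.na(fib[, 1]))
  if (length(bad)) {
    e <- mesh$nodes[tri[bad, 2], , drop = FALSE] - mesh$nodes[tri[bad, 1], , drop = FALSE]
    fib[bad, ] <- e / rownorms(e)
  }

  mesh$region <- region
  mesh$fiber <- fib
  mesh
}

## Sign-aligned Laplacian relaxation of a direction field on a triangle
## subset; keeps vectors in-plane and unit.  Deterministic.
smooth_fiber_patch <- function(mesh, fib, idx, normals, iters = 60) {
  if (length(idx) < 2) return(fib)
  tri <- mesh$triangles[idx, , drop = FALSE]
  de <- directed_edges(tri)
  key <- undirected_key(de)
  tid <- rep(seq_along(idx), 3)
  sp <- split(tid, key)
  prs <- do.call(rbind, sp[lengths(sp) == 2])
  if (is.null(prs) || nrow(prs) == 0) return(fib)
  f <- fib[idx, , drop = FALSE]
  n <- normals[idx, , drop = FALSE]
  for (it in seq_len(iters)) {
    acc <- f
    fa <- f[prs[, 1], , drop = FALSE]; fb <- f[prs[, 2], , drop = FALSE]
    s <- sign(rowSums(fa * fb)); s[s == 0] <- 1
    contrib_a <- fb * s
    contrib_b <- fa * s
    for (k in 1:3) {
      acc[, k] <- acc[, k] +
        unname(tapply(contrib_a[, k], prs[, 1], sum)[as.character(seq_along(idx))]) %|NA|% 0 +
        unname(tapply(contrib_b[, k], prs[, 2], sum)[as.character(seq_along(idx))]) %|NA|% 0
    }
    acc <- acc - n * rowSums(acc * n)
    nr <- rownorms(acc)
    keep <- nr > 1e-9
    f[keep, ] <- acc[keep, , drop = FALSE] / nr[keep]
  }
  fib[idx, ] <- f
  fib
}

`%|NA|%` <- function(a, b) { a[is.na(a)] <- b; a }

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Default tissue conduction table
#'
#' Monodomain diffusivities per region in S/(cm pF), longitudinal and
#' transverse, plus the intracellular values used for equivalent-dipole
#' strengths.  The two proximal coronary-sinus bridges carry the reported
#' 0.0060 longitudinal conductivity, 7.5 times the 0.0008 of the four distal
#' bridges; fast bundles (crista terminalis, Bachmann's bundle) are strongly
#' anisotropic, and working myocardium is about 0.003 with a 2.5:1 anisotropy
#' ratio.
#'
#' @return data.frame with columns `region`, `sigma_l`, `sigma_t`,
#'   `sigma_i_l`, `sigma_i_t`.
#' @export
default_tissue_table <- function() {
  t <- rbind(
    SAN         = c(0.0012, 0.0008),
    CT          = c(0.0090, 0.0014),
    BB_R        = c(0.0090, 0.0018),
    BB_L        = c(0.0090, 0.0018),
    RA_WALL     = c(0.0030, 0.0012),
    RAA         = c(0.0030, 0.0012),
    SVC         = c(0.0020, 0.0010),
    IVC         = c(0.0020, 0.0010),
    TV_RING     = c(0.0025, 0.0012),
    FO          = c(0.0030, 0.0020),
    RA_SEPTUM   = c(0.0030, 0.0012),
    LA_WALL     = c(0.0030, 0.0012),
    LAA         = c(0.0030, 0.0012),
    PV_LSPV     = c(0.0020, 0.0010),
    PV_LIPV     = c(0.0020, 0.0010),
    PV_RSPV     = c(0.0020, 0.0010),
    PV_RIPV     = c(0.0020, 0.0010),
    MV_RING     = c(0.0025, 0.0012),
    LA_POST     = c(0.0030, 0.0015),
    CS_SLEEVE   = c(0.0045, 0.0015),
    BRIDGE_PROX = c(0.0060, 0.0020),
    BRIDGE_DIST = c(0.0008, 0.0004)
  )
  data.frame(region = rownames(t), sigma_l = t[, 1], sigma_t = t[, 2],
             sigma_i_l = 2 * t[, 1], sigma_i_t = 2 * t[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the per-triangle anisotropic conductivity field
#'
#' @param mesh an annotated `atrial_mesh` (regions and fibers assigned).
#' @param tissue_table data.frame as returned by [default_tissue_table()];
#'   must cover every region present in the mesh.
#' @return object of class `conductivity_field` with per-triangle `sigma_l`,
#'   `sigma_t`, `sigma_i_l`, `sigma_i_t` and a `tensor(e)` accessor building
#'   the in-plane 3x3 tensor `sigma_t I_plane + (sigma_l - sigma_t) f f^T`.
#' @export
build_conductivity <- function(mesh, tissue_table = default_tissue_table()) {
  if (anyNA(mesh$region)) validation_error("mesh has unlabeled triangles")
  if (anyNA(mesh$fiber)) validation_error("mesh has unassigned fibers")
  missing <- setdiff(unique(mesh$region), tissue_table$region)
  if (length(missing))
    config_error(paste("tissue table missing regions:", paste(missing, collapse = ", ")))
  if (any(tissue_table$sigma_t > tissue_table$sigma_l) ||
      any(tissue_table$sigma_i_t > tissue_table$sigma_i_l))
    validation_error("sigma_t > sigma_l in tissue table")
  if (any(tissue_table$sigma_t <= 0)) validation_error("non-positive conductivity")
  i <- match(mesh$region, tissue_table$region)
  geo <- triangle_normals_areas(mesh$nodes, mesh$triangles)
  structure(list(
    sigma_l = tissue_table$sigma_l[i],
    sigma_t = tissue_table$sigma_t[i],
    sigma_i_l = tissue_table$sigma_i_l[i],
    sigma_i_t = tissue_table$sigma_i_t[i],
    fiber = mesh$fiber,
    normal = geo$normals,
    table = tissue_table
  ), class = "conductivity_field")
}

#' In-plane conductivity tensor of one triangle
#'
#' @param cond a `conductivity_field`.
#' @param e triangle index.
#' @param intracellular use the intracellular values.
#' @return 3x3 symmetric tensor, rank 2 in the triangle plane.
#' @export
conductivity_tensor <- function(cond, e, intracellular = FALSE) {
  f <- cond$fiber[e, ]
  n <- cond$normal[e, ]
  t <- pracma_cross(n, f)
  sl <- if (intracellular) cond$sigma_i_l[e] else cond$sigma_l[e]
  st <- if (intracellular) cond$sigma_i_t[e] else cond$sigma_t[e]
  sl * tcrossprod(f) + st * tcrossprod(t)
}
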