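## Synthetic biatrial surface geometry.
##
## Two ellipsoidal chambers (RA, LA) carry valve/vein orifices (open holes)
## and are joined by stitched tube connections standing in for Bachmann's
## bundle, the fossa ovalis rim and six coronary-sinus--left-atrium bridges
## (two proximal, four distal).  The torso frame is: +x patient left,
## +y posterior, +z superior; units mm.

#' Geometry parameters for the synthetic biatrial model
#'
#' Returns the default parameter set describing the two chambers, their
#' orifices (valve and vein openings, which remain open boundary loops) and
#' the interatrial connections (closed tube bridges).  Values can be
#' overridden by name.
#'
#' @param edge_length target triangle edge length in mm (default 2).
#' @param seed integer seed controlling the (deterministic) discretization.
#' @param single_chamber if `TRUE`, build only the RA ellipsoid.
#' @param ... named overrides of the returned list entries.
#' @return a list of class `geometry_params`.
#' @export
geometry_params <- function(edge_length = 2, seed = 42, single_chamber = FALSE, ...) {
  p <- list(
    edge_length = edge_length,
    seed = as.integer(seed),
    single_chamber = single_chamber,
    ra = list(center = c(-24, 0, 0), semi = c(22, 20, 26)),
    la = list(center = c( 24, 0, 0), semi = c(21, 19, 24)),
    orifices = list(
      SVC  = list(chamber = "ra", dir = c(0.15, -0.10, 1.00), radius = 5.0),
      IVC  = list(chamber = "ra", dir = c(-0.15, 0.10, -1.00), radius = 5.5),
      TV   = list(chamber = "ra", dir = c(0.30, -0.85, -0.45), radius = 9.0),
      MV   = list(chamber = "la", dir = c(-0.18, -0.80, -0.58), radius = 9.0),
      LSPV = list(chamber = "la", dir = c(0.18, 0.80, 0.58), radius = 3.4),
      LIPV = list(chamber = "la", dir = c(0.62, 0.80, 0.00), radius = 3.4),
      RSPV = list(chamber = "la", dir = c(-0.48, 0.60, 0.90), radius = 3.4),
      RIPV = list(chamber = "la", dir = c(-0.55, 0.80, 0.30), radius = 3.4)
    ),
    connections = local({
      ## six CS-LA bridges arc from the anterior-inferior septum towards the
      ## posterior wall; two proximal (fast) + four distal (slow)
      alpha <- c(26, 40, 50, 59, 67, 74) * pi / 180
      phi <- c(-60, -27, 5, 33, 59, 84) * pi / 180
      bridges <- lapply(1:6, function(i) {
        u <- c(cos(alpha[i]), sin(alpha[i]) * sin(phi[i]),
               -sin(alpha[i]) * cos(phi[i]))
        list(ra_dir = u, la_dir = u * c(-1, 1, 1), radius = 1.8,
             label = if (i <= 2) "BRIDGE_PROX" else "BRIDGE_DIST")
      })
      names(bridges) <- paste0("CS_BRIDGE_", 1:6)
      c(list(
        BB = list(ra_dir = c(0.90, -0.25, 0.45), la_dir = c(-0.90, -0.25, 0.45),
                  radius = 4.0, label = c("BB_R", "BB_L")),
        FO = list(ra_dir = c(1.00, 0.15, 0.05), la_dir = c(-1.00, 0.15, 0.05),
                  radius = 2.8, label = "FO")
      ), bridges)
    })
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  class(p) <- "geometry_params"
  p
}

## Point on the ellipsoid surface in direction `dir` from its center.
ellipsoid_anchor <- function(chamber, dir) {
  u <- normalize(dir)
  t <- 1 / sqrt(sum((u / chamber$semi)^2))
  chamber$center + t * u
}

## Seeded random rotation matrix (det +1).
random_rotation <- function(seed) {
  with_seed(seed, {
    m <- matrix(rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

## Triangulated ellipsoid chamber at the requested resolution.
build_chamber <- function(chamber, edge_length, seed) {
  rmean <- mean(chamber$semi)
  k <- max(1, ceiling(log2(1.0514 * rmean / edge_length)))
  ico <- icosphere(k)
  rot <- random_rotation(seed)
  v <- ico$nodes %*% t(rot)
  v <- sweep(v, 2, chamber$semi, `*`)
  v <- sweep(v, 2, chamber$center, `+`)
  ## enforce outward orientation
  g <- triangle_normals_areas(v, ico$triangles)
  cen <- triangle_centroids(v, ico$triangles)
  out <- sweep(cen, 2, chamber$center)
  flip <- rowSums(g$normals * out) < 0
  tri <- ico$triangles
  if (mean(flip) > 0.5) tri <- tri[, c(1, 3, 2)]
  list(nodes = v, triangles = tri)
}

## Carve a cap: remove the star of all vertices within `radius` mm of the
## anchor (at least the nearest vertex).  Returns the updated triangle set and
## the removed-vertex set.
carve_cap <- function(nodes, tri, anchor, radius, min_vertices = 1) {
  d <- sqrt(colSums((t(nodes) - anchor)^2))
  vset <- which(d <= radius)
  if (length(vset) < min_vertices) vset <- order(d)[seq_len(min_vertices)]
  keep <- star_removal(tri, vset)
  if (length(keep) == nrow(tri))
    geometry_error("cap removal produced no hole (radius too small for mesh resolution)")
  list(triangles = tri[keep, , drop = FALSE], vset = vset)
}

## Build intermediate rings and zipper bands for one tube connection.
## The tube centerline is a cubic Bezier that leaves each chamber along its
## outward surface normal (so grazing-angle connections do not fold back over
## the chamber wall); rings are carried on a rotation-minimizing frame.
## Returns new nodes, band triangles and per-triangle axial fraction.
build_tube <- function(nodes, loopA, loopB, edge_length, ref_edges,
                       normalA, normalB) {
  cA <- colMeans(nodes[loopA, , drop = FALSE])
  cB <- colMeans(nodes[loopB, , drop = FALSE])
  L0 <- vnorm(cB - cA)
  d <- min(max(L0 / 3, 1.5), 8)
  P0 <- cA; P1 <- cA + d * normalA; P2 <- cB + d * normalB; P3 <- cB
  bez <- function(f) {
    outer((1 - f)^3, P0) + outer(3 * f * (1 - f)^2, P1) +
      outer(3 * f^2 * (1 - f), P2) + outer(f^3, P3)
  }
  ## arc length by fine sampling
  fs_fine <- seq(0, 1, length.out = 200)
  pts <- bez(fs_fine)
  seg <- rownorms(pts[-1, , drop = FALSE] - pts[-200, , drop = FALSE])
  arclen <- c(0, cumsum(seg))
  Ltot <- arclen[200]
  n_rings <- max(0, round(Ltot / edge_length) - 1)
  rA <- mean(sqrt(colSums((t(nodes[loopA, , drop = FALSE]) - cA)^2)))
  rB <- mean(sqrt(colSums((t(nodes[loopB, , drop = FALSE]) - cB)^2)))

  new_nodes <- NULL
  loops <- list(loopA)
  n0 <- nrow(nodes)
  if (n_rings > 0) {
    nA <- length(loopA); nB <- length(loopB)
    ## polar profile of each rim in its local frame (periodic interpolant),
    ## so rings loft between the true rim shapes instead of circles
    t0 <- normalize(normalA)
    ref <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- normalize(ref - sum(ref * t0) * t0)
    profile_of <- function(loop, cen, tang, e1l) {
      e2l <- pracma_cross(tang, e1l)
      p <- sweep(nodes[loop, , drop = FALSE], 2, cen)
      th <- atan2(p %*% e2l, p %*% e1l)[, 1]
      rr <- sqrt(rowSums(p^2) - (p %*% tang)[, 1]^2)
      o <- order(th)
      list(th = th[o], r = rr[o])
    }
    interp_profile <- function(prof, th) {
      thx <- c(prof$th - 2 * pi, prof$th, prof$th + 2 * pi)
      rx <- rep(prof$r, 3)
      stats::approx(thx, rx, xout = th)$y
    }
    profA <- profile_of(loopA, cA, t0, e1)
    ## precompute stations and parallel-transported frames
    stations <- lapply(seq_len(n_rings), function(i) {
      s_target <- Ltot * i / (n_rings + 1)
      f <- stats::approx(arclen, fs_fine, xout = s_target)$y
      eps <- 1e-4
      list(f = f, cen = as.numeric(bez(f)),
           tang = normalize(as.numeric(bez(min(f + eps, 1)) - bez(max(f - eps, 0)))))
    })
    e1c <- e1
    for (i in seq_len(n_rings)) {
      e1c <- normalize(e1c - sum(e1c * stations[[i]]$tang) * stations[[i]]$tang)
      stations[[i]]$e1 <- e1c
      stations[[i]]$e2 <- pracma_cross(stations[[i]]$tang, e1c)
    }
    tB <- normalize(-normalB)
    e1B <- normalize(e1c - sum(e1c * tB) * tB)
    profB <- profile_of(loopB, cB, tB, e1B)
    m <- max(6, nA, nB)
    th <- 2 * pi * (seq_len(m) - 1) / m - pi
    for (i in seq_len(n_rings)) {
      st <- stations[[i]]
      fr <- i / (n_rings + 1)
      ## blend rim profiles, relaxing towards a circle mid-tube
      w <- 4 * fr * (1 - fr)
      rprof <- (1 - fr) * interp_profile(profA, th) + fr * interp_profile(profB, th)
      rcirc <- (1 - fr) * rA + fr * rB
      r <- (1 - w) * rprof + w * rcirc
      ring <- sweep(outer(cos(th), st$e1) * r + outer(sin(th), st$e2) * r, 2, st$cen, `+`)
      idx <- n0 + nrow(new_nodes %||% matrix(0, 0, 3)) + seq_len(m)
      new_nodes <- rbind(new_nodes, ring)
      loops[[length(loops) + 1]] <- idx
    }
  }
  loops[[length(loops) + 1]] <- loopB
  all_nodes <- rbind(nodes, new_nodes)
  bands <- NULL
  frac <- NULL
  ref_cur <- ref_edges
  for (i in seq_len(length(loops) - 1)) {
    band <- zipper_loops(all_nodes, loops[[i]], loops[[i + 1]])
    band <- orient_band(band, ref_cur)
    cen <- triangle_centroids(all_nodes, band)
    axis0 <- (cB - cA) / L0
    f <- as.numeric(sweep(cen, 2, cA) %*% axis0) / L0
    bands <- rbind(bands, band)
    frac <- c(frac, f)
    ref_cur <- directed_edges(band)
  }
  list(new_nodes = new_nodes, triangles = bands, frac = frac)
}

## Extract every boundary loop and assign each to its nearest anchor point.
## Errors if two anchors claim the same loop (merged holes) or a loop is
## unaccounted for.
extract_anchor_loops <- function(nodes, tri, anchors) {
  aud <- mesh_audit(nodes, tri)
  be <- aud$boundary_edges
  loops <- boundary_loops_from_edges(be)
  if (length(loops) != length(anchors))
    geometry_error(sprintf("expected %d boundary loops, found %d (holes merged or missing)",
                           length(anchors), length(loops)))
  cents <- t(vapply(loops, function(l) colMeans(nodes[l, , drop = FALSE]), numeric(3)))
  out <- list()
  claimed <- rep(FALSE, length(loops))
  for (nm in names(anchors)) {
    d <- sqrt(colSums((t(cents) - anchors[[nm]]$point)^2))
    j <- which.min(d)
    if (claimed[j]) geometry_error("two anchors share one boundary loop (overlap)")
    claimed[j] <- TRUE
    out[[nm]] <- loops[[j]]
  }
  out
}

#' Build the synthetic biatrial surface mesh
#'
#' Generates two triangulated ellipsoidal chambers, carves the configured
#' orifices (which remain open boundary loops) and the connection ports, and
#' stitches the interatrial tubes: one Bachmann-bundle band, one fossa-ovalis
#' rim and six coronary-sinus bridges (two proximal, four distal).  Connection
#' triangles are pre-labelled; chamber triangles are labelled later by
#' [assign_fibers_and_regions()].
#'
#' @param params a [geometry_params()] list.
#' @return an object of class `atrial_mesh` with fields `nodes` (n x 3, mm),
#'   `triangles` (nt x 3, 1-based), `region` (per-triangle character, `NA`
#'   until assigned except connection tubes), `fiber` (nt x 3, `NA` until
#'   assigned), `atrium` (per-node `"RA"`/`"LA"`), `orifices` (named list of
#'   ordered node loops) and `meta`.
#' @export
build_biatrial_mesh <- function(params = geometry_params()) {
  if (length(params$orifices) > 0) {
    rmin <- min(vapply(params$orifices, function(o) o$radius, numeric(1)))
    if (params$edge_length > rmin)
      geometry_error("target edge length exceeds the smallest orifice radius")
  }
  check_anchor_overlaps(params)

  ra <- build_chamber(params$ra, params$edge_length, params$seed)
  n_ra <- nrow(ra$nodes)
  if (params$single_chamber) {
    nodes <- ra$nodes; tri <- ra$triangles
    atrium <- rep("RA", n_ra)
    anchors <- list()
    for (nm in names(params$orifices)) {
      o <- params$orifices[[nm]]
      if (o$chamber != "ra") next
      anchors[[nm]] <- list(point = ellipsoid_anchor(params$ra, o$dir))
      cc <- carve_cap(nodes, tri, anchors[[nm]]$point, o$radius)
      tri <- cc$triangles
    }
    orifice_loops <- if (length(anchors)) extract_anchor_loops(nodes, tri, anchors) else list()
    keep_nodes <- sort(unique(as.vector(tri)))
    remap <- match(seq_len(nrow(nodes)), keep_nodes)
    tri <- matrix(remap[tri], ncol = 3)
    orifice_loops <- lapply(orifice_loops, function(l) remap[l])
    mesh <- new_atrial_mesh(nodes[keep_nodes, , drop = FALSE], tri, atrium[keep_nodes],
                            orifice_loops, region = rep(NA_character_, nrow(tri)), params)
    return(mesh)
  }

  la <- build_chamber(params$la, params$edge_length, params$seed + 1L)
  nodes <- rbind(ra$nodes, la$nodes)
  tri_ra <- ra$triangles
  tri_la <- la$triangles + n_ra
  atrium <- c(rep("RA", n_ra), rep("LA", nrow(la$nodes)))

  ## carve orifices and connection ports per chamber
  anchors <- list()
  for (nm in names(params$orifices)) {
    o <- params$orifices[[nm]]
    ch <- if (o$chamber == "ra") params$ra else params$la
    anchors[[nm]] <- list(point = ellipsoid_anchor(ch, o$dir), radius = o$radius,
                          chamber = o$chamber, type = "orifice")
  }
  for (nm in names(params$connections)) {
    cn <- params$connections[[nm]]
    anchors[[paste0(nm, "_ra")]] <- list(point = ellipsoid_anchor(params$ra, cn$ra_dir),
                                         radius = cn$radius, chamber = "ra", type = "port")
    anchors[[paste0(nm, "_la")]] <- list(point = ellipsoid_anchor(params$la, cn$la_dir),
                                         radius = cn$radius, chamber = "la", type = "port")
  }
  for (nm in names(anchors)) {
    a <- anchors[[nm]]
    mv <- if (a$type == "port") 3 else 1
    if (a$chamber == "ra") {
      cc <- carve_cap(nodes, tri_ra, a$point, a$radius, mv)
      tri_ra <- cc$triangles
    } else {
      cc <- carve_cap(nodes, tri_la, a$point, a$radius, mv)
      tri_la <- cc$triangles
    }
  }
  ## loops extracted after all cuts so merged holes are detected
  loops <- extract_anchor_loops(nodes, rbind(tri_ra, tri_la), anchors)
  tri <- rbind(tri_ra, tri_la)
  region <- rep(NA_character_, nrow(tri))

  ## stitch connections
  aud <- mesh_audit(nodes, tri)
  bed <- aud$boundary_edges
  conn_id <- rep(NA_character_, nrow(tri))
  conn_axes <- list()
  for (nm in names(params$connections)) {
    cn <- params$connections[[nm]]
    loopA <- loops[[paste0(nm, "_ra")]]
    loopB <- loops[[paste0(nm, "_la")]]
    ref <- bed[bed[, 1] %in% loopA & bed[, 2] %in% loopA, , drop = FALSE]
    tube <- build_tube(nodes, loopA, loopB, params$edge_length, ref,
                       ellipsoid_normal_at(params$ra, cn$ra_dir),
                       ellipsoid_normal_at(params$la, cn$la_dir))
    if (!is.null(tube$new_nodes)) {
      half <- tube$frac  # per-triangle fraction along RA->LA axis
      new_idx <- nrow(nodes) + seq_len(nrow(tube$new_nodes))
      ## ring-node atrium by axial position
      cA <- colMeans(nodes[loopA, , drop = FALSE])
      cB <- colMeans(nodes[loopB, , drop = FALSE])
      axisv <- (cB - cA) / vnorm(cB - cA)
      f_nodes <- as.numeric(sweep(tube$new_nodes, 2, cA) %*% axisv) / vnorm(cB - cA)
      atrium <- c(atrium, ifelse(f_nodes <= 0.5, "RA", "LA"))
      nodes <- rbind(nodes, tube$new_nodes)
    }
    lab <- cn$label
    tri_lab <- if (length(lab) == 2) ifelse(tube$frac <= 0.5, lab[1], lab[2]) else rep(lab, length(tube$frac))
    tri <- rbind(tri, tube$triangles)
    region <- c(region, tri_lab)
    conn_id <- c(conn_id, rep(nm, nrow(tube$triangles)))
    cA2 <- colMeans(nodes[loopA, , drop = FALSE])
    cB2 <- colMeans(nodes[loopB, , drop = FALSE])
    conn_axes[[nm]] <- list(axis = normalize(cB2 - cA2), ends = rbind(cA2, cB2))
  }

  orifice_loops <- loops[names(params$orifices)]
  ## drop carved-out (now isolated) nodes
  keep_nodes <- sort(unique(as.vector(tri)))
  remap <- match(seq_len(nrow(nodes)), keep_nodes)
  tri <- matrix(remap[tri], ncol = 3)
  orifice_loops <- lapply(orifice_loops, function(l) remap[l])
  mesh <- new_atrial_mesh(nodes[keep_nodes, , drop = FALSE], tri, atrium[keep_nodes],
                          orifice_loops, region, params)
  mesh$conn_id <- conn_id
  mesh$meta$conn_axes <- conn_axes
  mesh
}

new_atrial_mesh <- function(nodes, tri, atrium, orifices, region, params) {
  dimnames(nodes) <- NULL
  structure(list(
    nodes = nodes,
    triangles = tri,
    region = region,
    conn_id = rep(NA_character_, nrow(tri)),
    fiber = matrix(NA_real_, nrow(tri), 3),
    atrium = atrium,
    orifices = orifices,
    meta = list(params = params)
  ), class = "atrial_mesh")
}

## Pairwise anchor-overlap pre-check, in mm on the chamber surfaces.
check_anchor_overlaps <- function(params) {
  pts <- list(); rad <- c(); cham <- c()
  for (nm in names(params$orifices)) {
    o <- params$orifices[[nm]]
    ch <- if (o$chamber == "ra") params$ra else params$la
    pts[[nm]] <- ellipsoid_anchor(ch, o$dir); rad[nm] <- o$radius; cham[nm] <- o$chamber
  }
  if (!params$single_chamber) {
    for (nm in names(params$connections)) {
      cn <- params$connections[[nm]]
      pts[[paste0(nm, "_ra")]] <- ellipsoid_anchor(params$ra, cn$ra_dir)
      rad[paste0(nm, "_ra")] <- cn$radius; cham[paste0(nm, "_ra")] <- "ra"
      pts[[paste0(nm, "_la")]] <- ellipsoid_anchor(params$la, cn$la_dir)
      rad[paste0(nm, "_la")] <- cn$radius; cham[paste0(nm, "_la")] <- "la"
    }
  }
  nms <- names(pts)
  margin <- 2 * params$edge_length
  for (i in seq_along(nms)) for (j in seq_len(i - 1)) {
    if (cham[nms[i]] != cham[nms[j]]) next
    d <- vnorm(pts[[nms[i]]] - pts[[nms[j]]])
    if (d < rad[nms[i]] + rad[nms[j]] + margin)
      geometry_error(sprintf("orifices/ports '%s' and '%s' overlap (separation %.1f mm)",
                             nms[i], nms[j], d))
  }
  invisible(TRUE)
}

#' Validate the structural invariants of an atrial mesh
#'
#' Checks triangle validity, manifoldness, orientation, boundary placement
#' (boundary edges only on declared orifice loops), node usage and (when
#' regions are assigned) that RA and LA connect only through interatrial
#' connection triangles.
#'
#' @param mesh an `atrial_mesh`.
#' @return invisibly `TRUE`; raises a geometry error on violation.
#' @export
validate_atrial_mesh <- function(mesh) {
  tri <- mesh$triangles
  if (any(tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3]))
    geometry_error("triangle with repeated vertex")
  if (max(tri) > nrow(mesh$nodes) || min(tri) < 1)
    geometry_error("triangle references a missing node")
  used <- tabulate(tri, nbins = nrow(mesh$nodes))
  if (any(used == 0)) geometry_error("isolated node present")
  aud <- mesh_audit(mesh$nodes, tri)
  if (!aud$manifold) geometry_error("mesh is not edge-manifold")
  if (!aud$oriented) geometry_error("mesh is not consistently oriented")
  declared <- unlist(mesh$orifices)
  if (nrow(aud$boundary_edges) > 0) {
    onb <- unique(as.vector(aud$boundary_edges))
    if (!all(onb %in% declared))
      geometry_error("boundary edges outside declared orifices")
  }
  if (!all(is.na(mesh$region))) {
    conn <- interatrial_labels()
    keep <- !(mesh$region %in% conn)
    comp <- node_components(nrow(mesh$nodes), tri[keep, , drop = FALSE])
    ra_comp <- unique(comp[mesh$atrium == "RA" & used > 0])
    la_comp <- unique(comp[mesh$atrium == "LA" & used > 0])
    sub_used <- unique(as.vector(tri[keep, , drop = FALSE]))
    ra_comp <- unique(comp[intersect(which(mesh$atrium == "RA"), sub_used)])
    la_comp <- unique(comp[intersect(which(mesh$atrium == "LA"), sub_used)])
    if (length(intersect(ra_comp, la_comp)) > 0)
      geometry_error("RA and LA remain connected outside interatrial triangles")
  }
  invisible(TRUE)
}

#' @export
print.atrial_mesh <- function(x, ...) {
  cat(sprintf("<atrial_mesh> %d nodes, %d triangles, %d orifices\n",
              nrow(x$nodes), nrow(x$triangles), length(x$orifices)))
  if (!all(is.na(x$region)))
    cat("  regions:", paste(sort(unique(stats::na.omit(x$region))), collapse = ", "), "\n")
  invisible(x)
}

interatrial_labels <- function() c("BB_R", "BB_L", "FO", "BRIDGE_PROX", "BRIDGE_DIST")
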