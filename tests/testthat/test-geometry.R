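test_that("closed single chamber is a topological sphere with the analytic area", {
  p <- geometry_params(single_chamber = TRUE, orifices = list(),
                       connections = list())
  m <- build_biatrial_mesh(p)
  V <- nrow(m$nodes)
  F_ <- nrow(m$triangles)
  E <- length(unique(undirected_key(directed_edges(m$triangles))))
  expect_identical(V - E + F_, 2L)
  aud <- mesh_audit(m$nodes, m$triangles)
  expect_true(aud$manifold)
  expect_true(aud$oriented)
  expect_identical(nrow(aud$boundary_edges), 0L)
  ## discretized area vs brute-force fine-sampling of the ellipsoid
  area <- sum(triangle_normals_areas(m$nodes, m$triangles)$areas)
  oracle <- ellipsoid_area_numeric(p$ra$semi)
  expect_lt(abs(area - oracle) / oracle, 0.02)
})

test_that("default biatrial mesh satisfies the structural invariants", {
  m <- get_default_mesh()
  expect_silent(validate_atrial_mesh(m))
  ## every node used, triangles valid
  expect_true(all(tabulate(m$triangles, nrow(m$nodes)) > 0))
  ## boundary loops exactly at the declared orifices
  aud <- mesh_audit(m$nodes, m$triangles)
  loops <- boundary_loops_from_edges(aud$boundary_edges)
  expect_identical(length(loops), length(m$meta$params$orifices))
  ## fibers unit and in-plane
  geo <- triangle_normals_areas(m$nodes, m$triangles)
  expect_lt(max(abs(rownorms(m$fiber) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(m$fiber * geo$normals))), 1e-6)
})

test_that("chamber surface area matches the fine-sampling oracle", {
  ## orifices-only configuration (no connection tubes): total area equals the
  ## two generating ellipsoids minus the orifice caps.  Star removal eats the
  ## one-ring of the selected vertices, so the effective cap radius is the
  ## declared radius plus about half an edge.
  p <- geometry_params(connections = list())
  m <- build_biatrial_mesh(p)
  area <- sum(triangle_normals_areas(m$nodes, m$triangles)$areas)
  edge <- 1.0514 * mean(p$ra$semi) / 16  # realized icosphere edge
  oracle <- ellipsoid_area_numeric(p$ra$semi) + ellipsoid_area_numeric(p$la$semi)
  for (o in p$orifices) oracle <- oracle - pi * (o$radius + edge / 2)^2
  expect_lt(abs(area - oracle) / oracle, 0.02)
})

test_that("removing interatrial triangles splits RA and LA across seeds", {
  for (seed in c(1, 7, 42)) {
    p <- geometry_params(seed = seed)
    m <- build_biatrial_mesh(p)
    keep <- !(m$region %in% interatrial_labels())
    comp <- triangle_components(m$triangles[keep, , drop = FALSE])
    expect_identical(length(unique(comp)), 2L)
  }
})

test_that("mesh generation is bit-reproducible for a fixed seed", {
  p <- geometry_params(seed = 3)
  m1 <- assign_fibers_and_regions(build_biatrial_mesh(p))
  m2 <- assign_fibers_and_regions(build_biatrial_mesh(p))
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$triangles, m2$triangles)
  expect_identical(m1$fiber, m2$fiber)
  expect_identical(m1$region, m2$region)
})

test_that("geometry errors are raised for bad parameter sets", {
  p <- geometry_params(edge_length = 5)  # exceeds smallest orifice radius
  expect_error(build_biatrial_mesh(p), class = "bspim_geometry_error")
  p2 <- geometry_params()
  p2$orifices$LIPV$dir <- p2$orifices$LSPV$dir  # overlapping orifices
  expect_error(build_biatrial_mesh(p2), class = "bspim_geometry_error")
})

test_that("regions are exhaustive and fibers are smooth within regions", {
  m <- get_default_mesh()
  expect_false(anyNA(m$region))
  expect_setequal(unique(m$region), atrial_region_labels())
  ## uniform latitudinal rule on a closed ellipsoid: fibers orthogonal to the
  ## pole axis
  p <- geometry_params(single_chamber = TRUE, orifices = list(),
                       connections = list())
  p$fiber_rule <- "latitudinal"
  ms <- assign_fibers_and_regions(build_biatrial_mesh(p), p)
  expect_lt(max(abs(ms$fiber %*% c(0, 0, 1))), 1e-6)
  ## brute-force edge sweep: within-region adjacent fiber angle <= 45 degrees
  de <- directed_edges(m$triangles)
  key <- undirected_key(de)
  tid <- rep(seq_len(nrow(m$triangles)), 3)
  sp <- split(tid, key)
  prs <- do.call(rbind, sp[lengths(sp) == 2])
  same <- m$region[prs[, 1]] == m$region[prs[, 2]]
  dotv <- abs(rowSums(m$fiber[prs[, 1], ] * m$fiber[prs[, 2], ]))
  ang <- acos(pmin(1, dotv)) * 180 / pi
  expect_lte(max(ang[same]), 45)
})

test_that("conductivity field honors the tissue table and bridge ratio", {
  m <- get_default_mesh()
  cond <- get_default_cond()
  expect_true(all(cond$sigma_l >= cond$sigma_t))
  expect_true(all(cond$sigma_t > 0))
  r <- unique(cond$sigma_l[m$region == "BRIDGE_PROX"]) /
    unique(cond$sigma_l[m$region == "BRIDGE_DIST"])
  expect_equal(r, 7.5, tolerance = 1e-12)
  ## missing region in table
  tab <- default_tissue_table()
  expect_error(build_conductivity(m, tab[tab$region != "CT", ]),
               class = "bspim_config_error")
  ## sigma_t > sigma_l rejected
  bad <- default_tissue_table()
  bad$sigma_t[1] <- bad$sigma_l[1] * 2
  expect_error(build_conductivity(m, bad), class = "bspim_validation_error")
})

test_that("conductivity tensors: isotropy, eigenvalues, permutation invariance", {
  m <- get_default_mesh()
  ## isotropic table: tensor equals c * in-plane projector
  tabi <- default_tissue_table()
  tabi$sigma_t <- tabi$sigma_l <- 0.004
  tabi$sigma_i_t <- tabi$sigma_i_l <- 0.008
  ci <- build_conductivity(m, tabi)
  geo <- triangle_normals_areas(m$nodes, m$triangles)
  for (e in c(1L, 777L, nrow(m$triangles))) {
    Tn <- conductivity_tensor(ci, e)
    proj <- diag(3) - tcrossprod(geo$normals[e, ])
    expect_equal(Tn, 0.004 * proj, tolerance = 1e-12)
  }
  ## anisotropic: eigenvalues in {0} U [min sigma_t, max sigma_l]
  cond <- get_default_cond()
  set.seed(11)
  for (e in sample.int(nrow(m$triangles), 50)) {
    ev <- eigen(conductivity_tensor(cond, e), symmetric = TRUE)$values
    ev <- sort(ev)
    expect_lt(abs(ev[1]), 1e-12)
    expect_gte(ev[2], min(cond$sigma_t) - 1e-12)
    expect_lte(ev[3], max(cond$sigma_l) + 1e-12)
  }
  ## permutation invariance of assembly
  perm <- with_seed(5, sample.int(nrow(m$triangles)))
  mp <- m
  mp$triangles <- m$triangles[perm, , drop = FALSE]
  mp$region <- m$region[perm]
  mp$fiber <- m$fiber[perm, , drop = FALSE]
  cp <- build_conductivity(mp)
  expect_equal(cp$sigma_l, cond$sigma_l[perm])
  expect_equal(cp$fiber, cond$fiber[perm, , drop = FALSE])
})

test_that("default focus catalog has the expected composition", {
  m <- get_default_mesh()
  cat_f <- place_foci(m)
  expect_identical(nrow(cat_f), 58L)
  expect_identical(sum(cat_f$atrium == "RA"), 31L)  # SAN + 30 ectopic RA
  expect_identical(sum(cat_f$atrium == "LA"), 27L)
  expect_setequal(unique(cat_f$region), atrial_region_labels())
  patches <- attr(cat_f, "patches")
  expect_true(all(lengths(patches) >= 1))
  ## every patch within one atrium, geodesically connected (BFS oracle)
  for (i in seq_along(patches)) {
    pp <- patches[[i]]
    expect_identical(unique(m$atrium[pp]), cat_f$atrium[i])
    if (length(pp) > 1) {
      sub <- m$triangles[apply(matrix(m$triangles %in% pp,
                                      ncol = 3), 1, all), , drop = FALSE]
      visited <- cat_f$center_node[i]
      repeat {
        nb <- unique(as.vector(sub[rowSums(matrix(sub %in% visited,
                                                  ncol = 3)) > 0, ]))
        nb <- intersect(nb, pp)
        if (all(nb %in% visited)) break
        visited <- union(visited, nb)
      }
      expect_setequal(visited, pp)
    }
  }
  ## duplicate ids rejected
  lay <- default_foci_layout()
  lay$sites$id[2] <- lay$sites$id[1]
  expect_error(place_foci(m, lay), class = "bspim_layout_error")
})

test_that("torso lead array has the declared structure and clearance", {
  m <- get_default_mesh()
  leads <- build_torso_leads(torso_params(), m)
  expect_identical(nrow(leads), 252L)
  expect_identical(sum(leads$side == "front"), 126L)
  expect_identical(sum(leads$side == "back"), 126L)
  al <- attr(leads, "aliases")
  expect_named(al, paste0("V", 1:6))
  expect_true(all(al >= 1 & al <= nrow(leads)))
  ## brute-force distance scan
  P <- lead_positions(leads)
  d2 <- outer(rowSums(P^2), rowSums(m$nodes^2), `+`) - 2 * P %*% t(m$nodes)
  expect_gte(sqrt(min(d2)), 20)
  ## degenerate 1x1 grid
  l2 <- build_torso_leads(torso_params(rows = 1, cols = 1))
  expect_identical(nrow(l2), 2L)
  expect_setequal(l2$side, c("front", "back"))
})
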