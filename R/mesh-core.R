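## Low-level triangulated-surface machinery shared by the geometry module.
## Nodes are stored as an n x 3 matrix in mm; triangles as an nt x 3 integer
## matrix of 1-based node indices (exported formats use 0-based indices).

## Unit icosphere by recursive subdivision of an icosahedron.
icosphere <- function(subdiv) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edge_key <- function(a, b) ifelse(a < b, a * (nv + 1) + b, b * (nv + 1) + a)
    e1 <- edge_key(f[, 1], f[, 2]); e2 <- edge_key(f[, 2], f[, 3])
    e3 <- edge_key(f[, 3], f[, 1])
    keys <- unique(c(e1, e2, e3))
    midx <- match(c(e1, e2, e3), keys)
    ka <- keys %/% (nv + 1); kb <- keys %% (nv + 1)
    mids <- (v[ka, , drop = FALSE] + v[kb, , drop = FALSE]) / 2
    mids <- mids / rownorms(mids)
    m1 <- nv + midx[seq_len(nrow(f))]
    m2 <- nv + midx[nrow(f) + seq_len(nrow(f))]
    m3 <- nv + midx[2 * nrow(f) + seq_len(nrow(f))]
    v <- rbind(v, mids)
    f <- rbind(cbind(f[, 1], m1, m3), cbind(f[, 2], m2, m1),
               cbind(f[, 3], m3, m2), cbind(m1, m2, m3))
  }
  list(nodes = v, triangles = f)
}

## Directed edge list (one row per triangle edge, in traversal order).
directed_edges <- function(tri) {
  rbind(cbind(tri[, 1], tri[, 2]), cbind(tri[, 2], tri[, 3]),
        cbind(tri[, 3], tri[, 1]))
}

undirected_key <- function(e) {
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  paste(a, b)
}

## Manifold / orientation audit.  Returns counts of defective edges and the
## boundary (edges used by exactly one triangle).
mesh_audit <- function(nodes, tri) {
  de <- directed_edges(tri)
  key <- undirected_key(de)
  cnt <- table(key)
  over <- sum(cnt > 2)
  boundary_keys <- names(cnt)[cnt == 1]
  ## orientation: an interior edge must appear once in each direction
  dkey <- paste(de[, 1], de[, 2])
  ddup <- sum(duplicated(dkey) | duplicated(dkey, fromLast = TRUE))
  list(
    n_nonmanifold_edges = over,
    n_misoriented_pairs = ddup / 2,
    boundary_edges = de[key %in% boundary_keys, , drop = FALSE],
    manifold = over == 0,
    oriented = ddup == 0
  )
}

## Order a set of boundary edges (directed, from the kept triangles) into
## closed loops of node indices.
boundary_loops_from_edges <- function(bedges) {
  if (nrow(bedges) == 0) return(list())
  remaining <- setNames(as.list(bedges[, 2]), as.character(bedges[, 1]))
  visited <- character(0)
  loops <- list()
  for (s in as.character(bedges[, 1])) {
    if (s %in% visited) next
    loop <- integer(0)
    cur <- s
    closed <- FALSE
    repeat {
      if (cur %in% visited) break
      visited <- c(visited, cur)
      loop <- c(loop, as.integer(cur))
      nx <- remaining[[cur]]
      if (is.null(nx)) break
      cur <- as.character(nx)
      if (cur == s) { closed <- TRUE; break }
    }
    if (closed && length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

triangle_centroids <- function(nodes, tri) {
  (nodes[tri[, 1], , drop = FALSE] + nodes[tri[, 2], , drop = FALSE] +
     nodes[tri[, 3], , drop = FALSE]) / 3
}

triangle_normals_areas <- function(nodes, tri) {
  e1 <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  e2 <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  cr <- rowcross(e1, e2)
  a2 <- rownorms(cr)
  if (any(a2 < 1e-12)) geometry_error("degenerate (zero-area) triangle")
  list(normals = cr / a2, areas = a2 / 2)
}

## Connected components of triangles through shared edges; returns a component
## id per triangle.
triangle_components <- function(tri) {
  nt <- nrow(tri)
  key <- undirected_key(directed_edges(tri))
  tid <- rep(seq_len(nt), 3)
  grp <- split(tid, key)
  parent <- seq_len(nt)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (g in grp) {
    if (length(g) > 1) {
      r <- find(g[1])
      for (o in g[-1]) { ro <- find(o); if (ro != r) parent[ro] <- r }
    }
  }
  vapply(seq_len(nt), find, integer(1))
}

## Node-level connected components (via triangle edges).
node_components <- function(nodes_n, tri) {
  parent <- seq_len(nodes_n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in 1:3) {
    a <- tri[, k]; b <- tri[, (k %% 3) + 1]
    for (i in seq_along(a)) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(nodes_n), find, integer(1))
}

## Remove the star of a vertex set: drop every triangle touching the set.
## Returns kept-triangle index vector.
star_removal <- function(tri, vset) {
  touch <- tri[, 1] %in% vset | tri[, 2] %in% vset | tri[, 3] %in% vset
  which(!touch)
}

## Zipper-stitch two node loops (given as ordered index vectors into `nodes`)
## into a tube band of triangles.  Loops are re-ordered by angle around the
## axis from centroid(A) to centroid(B).  Returns a triangle matrix.
zipper_loops <- function(nodes, loopA, loopB) {
  cA <- colMeans(nodes[loopA, , drop = FALSE])
  cB <- colMeans(nodes[loopB, , drop = FALSE])
  axis <- normalize(cB - cA)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize(ref - sum(ref * axis) * axis)
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  ang <- function(loop, cen) {
    p <- sweep(nodes[loop, , drop = FALSE], 2, cen)
    atan2(p %*% e2, p %*% e1)[, 1]
  }
  aA <- ang(loopA, cA); aB <- ang(loopB, cB)
  oA <- order(aA); loopA <- loopA[oA]; aA <- aA[oA]
  oB <- order(aB); loopB <- loopB[oB]; aB <- aB[oB]
  ## align loop B start to loop A start
  shift <- which.min(abs(((aB - aA[1] + pi) %% (2 * pi)) - pi))
  idxB <- c(shift:length(loopB), seq_len(shift - 1))
  loopB <- loopB[idxB]; aB <- aB[idxB]
  aB <- aA[1] + ((aB - aA[1]) %% (2 * pi))
  aA <- aA[1] + ((aA - aA[1]) %% (2 * pi))
  ## sentinel wrap
  nA <- length(loopA); nB <- length(loopB)
  A <- c(loopA, loopA[1]); B <- c(loopB, loopB[1])
  tA <- c(aA, aA[1] + 2 * pi); tB <- c(aB, aB[1] + 2 * pi)
  tris <- matrix(0L, nA + nB, 3)
  i <- 1; j <- 1; r <- 0
  while (i <= nA || j <= nB) {
    adv_a <- (i <= nA) && (j > nB || tA[i + 1] <= tB[j + 1])
    r <- r + 1
    if (adv_a) {
      tris[r, ] <- c(A[i], A[i + 1], B[j]); i <- i + 1
    } else {
      tris[r, ] <- c(A[i], B[j + 1], B[j]); j <- j + 1
    }
  }
  tris[seq_len(r), , drop = FALSE]
}

## Flip a band of triangles if its edges agree in direction with reference
## directed edges (interior edges must oppose).
orient_band <- function(band, ref_edges) {
  refkey <- paste(ref_edges[, 1], ref_edges[, 2])
  de <- directed_edges(band)
  same <- sum(paste(de[, 1], de[, 2]) %in% refkey)
  opp  <- sum(paste(de[, 2], de[, 1]) %in% refkey)
  if (same > opp) band[, c(1, 3, 2)] else band
}
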