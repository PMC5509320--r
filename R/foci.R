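## The 58-site ectopic focus catalog: the sinoatrial node plus 30 right- and
## 27 left-atrial pacing sites spread over every region of the synthetic
## model, mirroring the anatomical coverage of clinical pacing studies.

#' Default focus layout: SAN + R1..R30 + L1..L27
#'
#' Region assignment of each focus id.  The per-region counts spread the 57
#' ectopic sites over all 21 region labels; within a region foci are placed
#' by deterministic farthest-point sampling.
#'
#' @param patch_area target stimulus patch area in mm^2 (default 6.8, the
#'   surface analog of the 6.8 mm^3 transmural stimulus volume).
#' @return a list of class `foci_layout` with `sites` (data.frame id, region,
#'   atrium) and `patch_radius` (mm).
#' @export
default_foci_layout <- function(patch_area = 6.8) {
  ra_regions <- c(rep("CT", 3), rep("RA_WALL", 8), rep("RAA", 2), rep("SVC", 2),
                  rep("IVC", 2), rep("TV_RING", 4), rep("RA_SEPTUM", 3),
                  rep("CS_SLEEVE", 2), "FO", "BB_R", "BRIDGE_PROX", "BRIDGE_DIST")
  la_regions <- c(rep("LA_WALL", 7), rep("LA_POST", 5), rep("LAA", 2),
                  rep("MV_RING", 4), rep("PV_LSPV", 2), rep("PV_LIPV", 2),
                  rep("PV_RSPV", 2), rep("PV_RIPV", 2), "BB_L")
  stopifnot(length(ra_regions) == 30, length(la_regions) == 27)
  sites <- rbind(
    data.frame(id = "SAN", region = "SAN", atrium = "RA"),
    data.frame(id = paste0("R", 1:30), region = ra_regions, atrium = "RA"),
    data.frame(id = paste0("L", 1:27), region = la_regions, atrium = "LA")
  )
  structure(list(sites = sites, patch_radius = sqrt(patch_area / pi)),
            class = "foci_layout")
}

## Deterministic farthest-point sampling of k nodes from a candidate set.
farthest_point_sample <- function(nodes, cand, k) {
  cen <- colMeans(nodes[cand, , drop = FALSE])
  d0 <- sqrt(colSums((t(nodes[cand, , drop = FALSE]) - cen)^2))
  picked <- cand[which.min(d0)]
  while (length(picked) < k) {
    dmin <- apply(vapply(picked, function(p)
      sqrt(colSums((t(nodes[cand, , drop = FALSE]) - nodes[p, ])^2)),
      numeric(length(cand))), 1, min)
    nxt <- cand[which.max(dmin)]
    picked <- c(picked, nxt)
  }
  picked
}

#' Place the ectopic focus catalog on the mesh
#'
#' @param mesh an annotated `atrial_mesh`.
#' @param layout a `foci_layout` (default [default_foci_layout()]).
#' @return object of class `foci_catalog`: data.frame with `id`,
#'   `center_node`, `radius`, `atrium`, `region`, plus attribute
#'   `patches` (list of node-index vectors, the geodesically connected
#'   stimulus patches).
#' @export
place_foci <- function(mesh, layout = default_foci_layout()) {
  sites <- layout$sites
  if (anyDuplicated(sites$id)) bspim_error("duplicate focus id", "bspim_layout_error")
  present <- unique(mesh$region)
  absent <- setdiff(unique(sites$region), present)
  if (length(absent))
    bspim_error(paste("layout references regions absent from the mesh:",
                      paste(absent, collapse = ", ")), "bspim_layout_error")

  tri <- mesh$triangles
  centers <- integer(nrow(sites))
  for (rg in unique(sites$region)) {
    rows <- which(sites$region == rg)
    for (atr in unique(sites$atrium[rows])) {
      rws <- rows[sites$atrium[rows] == atr]
      tmask <- mesh$region == rg
      nds <- unique(as.vector(tri[tmask, , drop = FALSE]))
      nds <- nds[mesh$atrium[nds] == atr]
      if (length(nds) == 0)
        bspim_error(sprintf("region %s has no %s nodes", rg, atr), "bspim_layout_error")
      picked <- farthest_point_sample(mesh$nodes, nds, min(length(rws), length(nds)))
      centers[rws] <- picked[((seq_along(rws) - 1) %% length(picked)) + 1]
    }
  }

  r <- layout$patch_radius
  patches <- lapply(seq_len(nrow(sites)), function(i) {
    c0 <- centers[i]
    d <- sqrt(colSums((t(mesh$nodes) - mesh$nodes[c0, ])^2))
    ball <- which(d <= max(r, 1e-9) & mesh$atrium == mesh$atrium[c0])
    if (!(c0 %in% ball)) ball <- c(c0, ball)
    ## keep the geodesically connected component containing the center
    sub <- tri[tri[, 1] %in% ball & tri[, 2] %in% ball & tri[, 3] %in% ball, , drop = FALSE]
    if (nrow(sub) == 0) return(c0)
    comp <- node_components(nrow(mesh$nodes), sub)
    inball <- ball[ball %in% as.vector(sub)]
    keep <- inball[comp[inball] == comp[c0]]
    sort(unique(c(c0, keep)))
  })

  cat_df <- data.frame(id = sites$id, center_node = centers, radius = r,
                       atrium = sites$atrium, region = sites$region,
                       stringsAsFactors = FALSE)
  structure(cat_df, patches = patches, class = c("foci_catalog", "data.frame"))
}

#' Focus 3-D centers (mm)
#' @param mesh an `atrial_mesh`.
#' @param catalog a `foci_catalog`.
#' @return numeric matrix (n_foci x 3).
#' @export
foci_centers <- function(mesh, catalog) {
  mesh$nodes[catalog$center_node, , drop = FALSE]
}
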