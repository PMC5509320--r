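## Torso lead array: a front + back electrode grid on an elliptic-cylinder
## torso surface, with precordial V1..V6 aliases snapped to the grid.

#' Torso lead-array parameters
#'
#' @param rows,cols grid size per side (default 14 x 9, i.e. 252 leads total).
#' @param torso_semi semi-axes of the torso cross-section ellipse (x lateral,
#'   y antero-posterior), mm.
#' @param z_range vertical extent of the grid relative to the atrial center, mm.
#' @param x_range lateral extent of the grid, mm.
#' @param center offset of the torso axis from the atrial center, mm.
#' @return list of class `torso_params`.
#' @export
torso_params <- function(rows = 14, cols = 9, torso_semi = c(160, 110),
                         z_range = c(-180, 160), x_range = c(-120, 120),
                         center = c(0, 0, 0)) {
  structure(list(rows = rows, cols = cols, torso_semi = torso_semi,
                 z_range = z_range, x_range = x_range, center = center),
            class = "torso_params")
}

#' Build the torso lead set
#'
#' Places `rows x cols` electrodes on the anterior (front) and posterior
#' (back) torso surface and assigns precordial aliases V1..V6 to the nearest
#' front-grid leads.
#'
#' @param params a [torso_params()] list.
#' @param mesh optional `atrial_mesh`; when given, leads are checked to lie
#'   at least 20 mm outside the atrial bounding sphere.
#' @return object of class `lead_set`: data.frame `label`, `x`, `y`, `z`,
#'   `side`, with attribute `aliases` (named lead indices for V1..V6).
#' @export
build_torso_leads <- function(params = torso_params(), mesh = NULL) {
  a <- params$torso_semi[1]; b <- params$torso_semi[2]
  xs <- seq(params$x_range[1], params$x_range[2], length.out = params$cols)
  zs <- seq(params$z_range[1], params$z_range[2], length.out = params$rows)
  g <- expand.grid(x = xs, z = zs)
  y <- b * sqrt(pmax(0, 1 - (g$x / a)^2))
  front <- data.frame(label = sprintf("F%02d_%02d",
                                      rep(seq_len(params$rows), each = params$cols),
                                      rep(seq_len(params$cols), params$rows)),
                      x = g$x, y = -y, z = g$z, side = "front",
                      stringsAsFactors = FALSE)
  back <- front
  back$label <- sub("^F", "B", front$label)
  back$y <- y
  back$side <- "back"
  leads <- rbind(front, back)
  leads$x <- leads$x + params$center[1]
  leads$y <- leads$y + params$center[2]
  leads$z <- leads$z + params$center[3]

  ## precordial aliases: canonical chest (x, z) positions projected onto the
  ## front grid (x left+, z superior+; atria near the origin)
  canon <- rbind(V1 = c(-25, -40), V2 = c(25, -40), V3 = c(40, -60),
                 V4 = c(55, -80), V5 = c(85, -80), V6 = c(120, -80))
  fr <- which(leads$side == "front")
  aliases <- apply(canon, 1, function(p) {
    fr[which.min((leads$x[fr] - p[1])^2 + (leads$z[fr] - p[2])^2)]
  })
  attr(leads, "aliases") <- aliases
  class(leads) <- c("lead_set", "data.frame")

  if (!is.null(mesh)) validate_lead_clearance(leads, mesh)
  leads
}

#' Check that all leads clear the atrial bounding sphere by 20 mm
#' @param leads a `lead_set`; @param mesh an `atrial_mesh`.
#' @return invisibly the minimum lead-to-node distance (mm).
#' @export
validate_lead_clearance <- function(leads, mesh) {
  ctr <- colMeans(mesh$nodes)
  rad <- max(sqrt(colSums((t(mesh$nodes) - ctr)^2)))
  p <- as.matrix(leads[, c("x", "y", "z")])
  d <- sqrt(colSums((t(p) - ctr)^2))
  if (any(d < rad + 20))
    geometry_error("lead inside (or within 20 mm of) the atrial bounding sphere")
  dm <- min(outer(rowSums(p^2), rowSums(mesh$nodes^2), `+`) - 2 * p %*% t(mesh$nodes))
  invisible(sqrt(max(dm, 0)))
}

lead_positions <- function(leads) as.matrix(leads[, c("x", "y", "z")])
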