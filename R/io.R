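## File interfaces.  Mesh: legacy ASCII VTK POLYDATA (with CELL_DATA arrays
## "region" and "fiber") and PLY (geometry only).  Tables: CSV with 0-based
## node/triangle indices.  Reports: JSON.  The binary container is R's native
## RDS (no HDF5 binding is assumed present).

#' Write an atrial mesh as legacy ASCII VTK POLYDATA
#'
#' Region labels are written as integer codes (SCALARS `region`); the
#' code-to-label table is embedded in the title line.  Fibers go into a
#' VECTORS array.  Indices are 0-based as per the format.
#'
#' @param mesh an `atrial_mesh`.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_mesh_vtk <- function(mesh, path) {
  labs <- sort(unique(stats::na.omit(mesh$region)))
  code <- match(mesh$region, labs) - 1L
  code[is.na(code)] <- -1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vtk DataFile Version 3.0", con)
  writeLines(paste("bspim atrial mesh; regions:", paste(labs, collapse = ",")), con)
  writeLines("ASCII", con)
  writeLines("DATASET POLYDATA", con)
  writeLines(sprintf("POINTS %d float", nrow(mesh$nodes)), con)
  utils::write.table(format(mesh$nodes, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  nt <- nrow(mesh$triangles)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_DATA %d", nt), con)
  writeLines("SCALARS region int 1", con)
  writeLines("LOOKUP_TABLE default", con)
  writeLines(as.character(code), con)
  if (!anyNA(mesh$fiber)) {
    writeLines("VECTORS fiber float", con)
    utils::write.table(format(mesh$fiber, digits = 9, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a legacy ASCII VTK POLYDATA mesh written by [write_mesh_vtk()]
#' @param path input file.
#' @return an `atrial_mesh` (without connection metadata).
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  labs <- character(0)
  m <- regmatches(ln[2], regexec("regions: (.*)$", ln[2]))[[1]]
  if (length(m) == 2) labs <- strsplit(m[2], ",")[[1]]
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], " +")[[1]][2])
  pts_txt <- scan(text = ln[(ip + 1):length(ln)], what = numeric(), n = 3 * np,
                  quiet = TRUE)
  nodes <- matrix(pts_txt, np, 3, byrow = TRUE)
  ig <- grep("^POLYGONS", ln)[1]
  nt <- as.integer(strsplit(ln[ig], " +")[[1]][2])
  tri_txt <- scan(text = ln[(ig + 1):length(ln)], what = integer(), n = 4 * nt,
                  quiet = TRUE)
  tri <- matrix(tri_txt, nt, 4, byrow = TRUE)[, 2:4] + 1L
  region <- rep(NA_character_, nt)
  ir <- grep("^SCALARS region", ln)
  if (length(ir)) {
    code <- scan(text = ln[(ir[1] + 2):length(ln)], what = integer(), n = nt,
                 quiet = TRUE)
    region <- ifelse(code >= 0, labs[code + 1], NA_character_)
  }
  fiber <- matrix(NA_real_, nt, 3)
  iv <- grep("^VECTORS fiber", ln)
  if (length(iv)) {
    fv <- scan(text = ln[(iv[1] + 1):length(ln)], what = numeric(), n = 3 * nt,
               quiet = TRUE)
    fiber <- matrix(fv, nt, 3, byrow = TRUE)
  }
  ## atrium flag recovered by x sign (RA left of the septum at x < 0)
  atr <- ifelse(nodes[, 1] < 0, "RA", "LA")
  structure(list(nodes = nodes, triangles = tri, region = region,
                 conn_id = rep(NA_character_, nt), fiber = fiber,
                 atrium = atr, orifices = list(), meta = list(params = NULL)),
            class = "atrial_mesh")
}

#' Write mesh geometry as ASCII PLY
#' @param mesh an `atrial_mesh`; @param path output file.
#' @return invisibly `path`.
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$nodes)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$nodes, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$triangles - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the focus catalog as CSV (0-based node indices)
#' @param catalog a `foci_catalog`; @param mesh the mesh; @param path file.
#' @return invisibly `path` (writer) / a data.frame (reader).
#' @export
write_catalog_csv <- function(catalog, mesh, path) {
  ctr <- foci_centers(mesh, catalog)
  df <- data.frame(id = catalog$id, center_node = catalog$center_node - 1L,
                   x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                   radius = catalog$radius, atrium = catalog$atrium,
                   region = catalog$region)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_csv
#' @export
read_catalog_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$center_node <- df$center_node + 1L
  df
}

#' Write a lead set as CSV
#' @param leads a `lead_set`; @param path file.
#' @export
write_leads_csv <- function(leads, path) {
  utils::write.csv(as.data.frame(leads), path, row.names = FALSE)
  invisible(path)
}

#' Write / read a BSPM as CSV (leads as rows, time columns stamped in ms)
#' @param bspm a `bspm`; @param path file.
#' @export
write_bspm_csv <- function(bspm, path) {
  df <- data.frame(lead = bspm$labels, bspm$Ve, check.names = FALSE)
  names(df)[-1] <- sprintf("t%.3f", bspm$times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bspm_csv
#' @export
read_bspm_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  times <- as.numeric(sub("^t", "", names(df)[-1]))
  structure(list(Ve = as.matrix(df[, -1, drop = FALSE]), times = times,
                 labels = df$lead, reference = "unknown", torso_sigma = NA,
                 stim_time = times[1]),
            class = "bspm")
}

#' Write a LAT map as node-indexed CSV
#' @param latmap a `lat_map`; @param path file.
#' @export
write_lat_csv <- function(latmap, path) {
  utils::write.csv(data.frame(node = seq_along(latmap$lat) - 1L,
                              lat_ms = latmap$lat), path, row.names = FALSE)
  invisible(path)
}

#' Write integral maps (one row per lead) as CSV
#' @param map a `bspim_map`; @param path file.
#' @export
write_bspim_csv <- function(map, path) {
  utils::write.csv(data.frame(lead = map$labels, value = map$values,
                              normalized = map$normalized), path,
                   row.names = FALSE)
  invisible(path)
}

#' Feature matrix CSV: id/x/y/z/atrium then one column per lead
#' @param features a `feature_matrix`; @param path file.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(id = features$ids, x = features$centers[, 1],
                   y = features$centers[, 2], z = features$centers[, 3],
                   atrium = features$atrium, features$X, check.names = FALSE)
  names(df)[-(1:5)] <- sprintf("lead%03d", seq_len(ncol(features$X)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lead_cols <- grep("^lead", names(df))
  structure(list(X = as.matrix(df[, lead_cols, drop = FALSE]),
                 ids = df$id,
                 centers = as.matrix(df[, c("x", "y", "z")]),
                 atrium = df$atrium),
            class = "feature_matrix")
}

#' Binary container (RDS)
#'
#' The spec's binary sidecar container; implemented with R's native
#' serialization since no HDF5 binding is available.
#' @param object any R object; @param path file.
#' @export
write_container <- function(object, path) { saveRDS(object, path); invisible(path) }

#' @rdname write_container
#' @export
read_container <- function(path) readRDS(path)

## ---- configuration (TOML subset) -------------------------------------------
## Supported: [section] headers, key = value with value one of: string
## ("..."), number, true/false, or a flat array [v1, v2, ...].

parse_toml_value <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[", s)) {
    inner <- sub("^\\[", "", sub("\\]$", "", s))
    if (trimws(inner) == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, parse_toml_value)))
  }
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  config_error(paste("cannot parse config value:", s))
}

#' Read a configuration file (TOML subset)
#'
#' Sections (`[geometry]`, `[tissue]`, `[protocol]`, `[leads]`, `[learning]`,
#' `[seeds]`) with `key = value` entries; values are strings, numbers,
#' booleans or flat arrays.
#'
#' @param path config file.
#' @return nested named list.
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  out <- list()
  section <- NULL
  for (l in ln) {
    if (grepl("^\\[.*\\]$", l)) {
      section <- gsub("^\\[|\\]$", "", l)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", l)) {
      kv <- regmatches(l, regexpr("=", l), invert = TRUE)[[1]]
      key <- trimws(kv[1]); val <- parse_toml_value(kv[2])
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    } else {
      config_error(paste("unparseable config line:", l))
    }
  }
  out
}

#' Write a configuration list in the TOML subset
#' @param config nested named list (one level of sections).
#' @param path output file.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) ifelse(v, "true", "false")
    else as.character(v)
  }
  lines <- character(0)
  for (s in names(config)) {
    if (is.list(config[[s]])) {
      lines <- c(lines, sprintf("[%s]", s))
      for (k in names(config[[s]])) {
        v <- config[[s]][[k]]
        val <- if (length(v) > 1) paste0("[", paste(fmt(v), collapse = ", "), "]")
               else fmt(v)
        lines <- c(lines, sprintf("%s = %s", k, val))
      }
    } else {
      lines <- c(lines, sprintf("%s = %s", s, fmt(config[[s]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
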