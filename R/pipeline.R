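## End-to-end experiment orchestration: geometry -> 58 activations -> BSPMs
## -> P-wave integral maps -> clustering -> stratified-CV classification.

#' Default run configuration
#'
#' @param mode `"eikonal"` (fast default) or `"monodomain"`.
#' @return nested list with sections geometry, tissue, protocol, leads,
#'   learning, seeds.
#' @export
run_config <- function(mode = "eikonal") {
  list(
    geometry = list(edge_length = 2, seed = 42),
    tissue = list(),          # overrides of default_tissue_table() by region
    protocol = list(mode = mode, n_beats = 2, BCL = 500, record_window = 350,
                    output_step = 1),
    leads = list(rows = 14, cols = 9),
    learning = list(k_min = 2, k_max = 6, algorithm = "kmeans", n_folds = 4,
                    C = 1, m_neighbors = 5, use_normalized = TRUE),
    seeds = list(geometry = 42, clustering = 0, cv = 0)
  )
}

apply_tissue_overrides <- function(tab, overrides) {
  for (rg in names(overrides)) {
    i <- match(rg, tab$region)
    if (is.na(i)) config_error(paste("unknown region in tissue overrides:", rg))
    v <- overrides[[rg]]
    tab$sigma_l[i] <- v[1]; tab$sigma_t[i] <- v[2]
    tab$sigma_i_l[i] <- 2 * v[1]; tab$sigma_i_t[i] <- 2 * v[2]
  }
  tab
}

#' Simulate all catalog foci and build the normalized feature matrix
#'
#' The workhorse shared by [run_full()] and the acceptance experiment:
#' for every focus, solve the activation (eikonal fast mode by default),
#' reconstruct voltage, project to the leads, and integrate the P-wave;
#' finally normalize the map set by its global range.
#'
#' @param mesh,cond,model,catalog,leads pipeline objects.
#' @param mode `"eikonal"` or `"monodomain"`.
#' @param protocol `stimulus_protocol` (monodomain mode and record window).
#' @param progress print per-focus progress.
#' @return list: `maps` (normalized `bspim_map`s), `features`
#'   (`feature_matrix`), `lats` (list of `lat_map`), `failures`.
#' @export
simulate_all_foci <- function(mesh, cond, model, catalog, leads,
                              mode = c("eikonal", "monodomain"),
                              protocol = stimulus_protocol(),
                              progress = FALSE) {
  mode <- match.arg(mode)
  B <- lead_transfer_operator(mesh, cond, leads)
  su <- if (mode == "eikonal") eikonal_setup(mesh, cond) else NULL
  maps <- list(); lats <- list(); failures <- list()
  for (i in seq_len(nrow(catalog))) {
    id <- catalog$id[i]
    res <- tryCatch({
      patch <- attr(catalog, "patches")[[i]]
      if (mode == "eikonal") {
        lm_ <- solve_eikonal(mesh, cond, patch, setup = su)
        tmax <- max(lm_$lat[is.finite(lm_$lat)])
        times <- seq(0, ceiling(tmax) + 5, by = protocol$output_step)
        tr <- lat_to_voltage(lm_, mesh, model, times)
      } else {
        proto <- stimulus_protocol(n_beats = protocol$n_beats,
                                   BCL = protocol$BCL, focus = id,
                                   record_window = protocol$record_window,
                                   output_step = protocol$output_step)
        tr <- solve_monodomain(mesh, cond, model, proto, catalog)
        lm_ <- compute_lat(tr)
      }
      fid <- detect_fiducials(lm_, stim_time = tr$stim_time)
      Ve <- B %*% tr$V
      Ve <- sweep(Ve, 2, colMeans(Ve))
      bs <- structure(list(Ve = Ve, times = tr$times, labels = leads$label,
                           reference = "mean", torso_sigma = 0.002,
                           stim_time = tr$stim_time), class = "bspm")
      list(map = pwave_integral(bs, fid, focus = id), lat = lm_)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      if (progress) message(sprintf("focus %s FAILED: %s", id, failures[[id]]))
    } else {
      maps[[id]] <- res$map
      lats[[id]] <- res$lat
      if (progress) message(sprintf("focus %s done (offset %.0f ms)", id,
                                    max(res$lat$lat)))
    }
  }
  ok_ids <- names(maps)
  maps <- normalize_set(maps)
  cat_ok <- catalog[match(ok_ids, catalog$id), , drop = FALSE]
  attr(cat_ok, "patches") <- attr(catalog, "patches")[match(ok_ids, catalog$id)]
  class(cat_ok) <- class(catalog)
  feats <- feature_matrix(maps, cat_ok, mesh)
  list(maps = maps, features = feats, lats = lats, failures = failures)
}

#' Run the full experiment
#'
#' @param config a [run_config()]-style list.
#' @param out_dir output directory (created if missing).
#' @param force rerun even if a manifest for the same config hash exists.
#' @param artifacts `"summary"` writes LAT and integral maps per focus;
#'   `"full"` additionally writes each BSPM; `"none"` writes only reports.
#' @param progress print progress.
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_full <- function(config = run_config(), out_dir = tempfile("bspim_run_"),
                     force = FALSE, artifacts = c("summary", "full", "none"),
                     progress = FALSE) {
  artifacts <- match.arg(artifacts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                                    (seq_len(nchar(cfg_json)) %% 97 + 1)) %% .Machine$integer.max)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, cfg_hash)) return(invisible(old))
  }
  t0 <- Sys.time()

  gp <- geometry_params(edge_length = config$geometry$edge_length,
                        seed = config$geometry$seed)
  mesh <- assign_fibers_and_regions(build_biatrial_mesh(gp))
  validate_atrial_mesh(mesh)
  tab <- apply_tissue_overrides(default_tissue_table(), config$tissue)
  cond <- build_conductivity(mesh, tab)
  catalog <- place_foci(mesh)
  leads <- build_torso_leads(torso_params(rows = config$leads$rows,
                                          cols = config$leads$cols), mesh)
  model <- membrane_model()
  proto <- stimulus_protocol(n_beats = config$protocol$n_beats,
                             BCL = config$protocol$BCL,
                             record_window = config$protocol$record_window,
                             output_step = config$protocol$output_step)
  sim <- simulate_all_foci(mesh, cond, model, catalog, leads,
                           mode = config$protocol$mode, protocol = proto,
                           progress = progress)

  lr <- config$learning
  sweep <- sweep_k(sim$features, k_range = lr$k_min:lr$k_max,
                   algorithm = lr$algorithm,
                   cluster_seed = config$seeds$clustering,
                   cv_seed = config$seeds$cv, n_folds = lr$n_folds,
                   m_neighbors = lr$m_neighbors)

  ## artifacts
  focus_records <- list()
  if (artifacts != "none") {
    for (id in names(sim$maps)) {
      fdir <- file.path(out_dir, id)
      dir.create(fdir, showWarnings = FALSE)
      write_lat_csv(sim$lats[[id]], file.path(fdir, "lat.csv"))
      write_bspim_csv(sim$maps[[id]], file.path(fdir, "bspim.csv"))
      focus_records[[id]] <- list(lat = file.path(id, "lat.csv"),
                                  bspim = file.path(id, "bspim.csv"))
    }
  }
  for (id in names(sim$failures))
    focus_records[[id]] <- list(error = sim$failures[[id]])
  write_features_csv(sim$features, file.path(out_dir, "features.csv"))
  utils::write.csv(as.data.frame(sweep)[, c("k", "coherent", "cv_accuracy",
                                            "misclassified")],
                   file.path(out_dir, "sweep.csv"), row.names = FALSE)
  write_mesh_vtk(mesh, file.path(out_dir, "mesh.vtk"))
  write_catalog_csv(catalog, mesh, file.path(out_dir, "catalog.csv"))
  write_leads_csv(leads, file.path(out_dir, "leads.csv"))

  manifest <- list(
    config_hash = cfg_hash,
    config = config,
    n_foci = nrow(catalog),
    n_complete = length(sim$maps),
    failures = sim$failures,
    focus_records = focus_records,
    sweep = lapply(seq_len(nrow(sweep)), function(i) as.list(sweep[i, ])),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = list(features = "features.csv", sweep = "sweep.csv",
                 mesh = "mesh.vtk", catalog = "catalog.csv",
                 leads = "leads.csv")
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(manifest, "features") <- sim$features
  attr(manifest, "sweep") <- sweep
  invisible(manifest)
}

#' Geometry parameters of the coarse test fixture
#'
#' A simplified biatrial model at ~3 mm resolution: five orifices, the
#' Bachmann bundle, fossa ovalis and two coronary-sinus bridges (one
#' proximal, one distal), 12 foci and a 60-lead array.
#'
#' @param seed discretization seed.
#' @return `geometry_params`.
#' @export
fixture_geometry_params <- function(seed = 7) {
  p <- geometry_params(edge_length = 2.98, seed = seed)
  p$orifices <- p$orifices[c("SVC", "IVC", "TV", "MV", "LSPV")]
  p$orifices$TV$radius <- 8
  p$orifices$MV$radius <- 8
  p$orifices$LSPV$radius <- 3.0
  b1 <- p$connections$CS_BRIDGE_1
  b2 <- p$connections$CS_BRIDGE_5
  p$connections <- c(p$connections[c("BB", "FO")],
                     list(CS_BRIDGE_1 = b1, CS_BRIDGE_2 = b2))
  p$connections$CS_BRIDGE_2$label <- "BRIDGE_DIST"
  p$connections$FO$ra_dir <- c(1.0, 0.42, -0.25)
  p$connections$FO$la_dir <- c(-1.0, 0.42, -0.25)
  p$connections$BB$ra_dir <- c(0.85, -0.32, 0.55)
  p$connections$BB$la_dir <- c(-0.85, -0.32, 0.55)
  p
}

#' Focus layout of the test fixture (12 foci)
#' @return a `foci_layout`.
#' @export
fixture_foci_layout <- function() {
  lay <- default_foci_layout()
  lay$sites <- rbind(
    data.frame(id = "SAN", region = "SAN", atrium = "RA"),
    data.frame(id = paste0("R", 1:7),
               region = c("CT", "RA_WALL", "RAA", "TV_RING", "RA_SEPTUM",
                          "CS_SLEEVE", "BRIDGE_DIST"), atrium = "RA"),
    data.frame(id = paste0("L", 1:4),
               region = c("LA_WALL", "LA_POST", "MV_RING", "BB_L"),
               atrium = "LA"))
  lay
}

#' Build the canned test fixture
#'
#' Coarse simplified biatrial mesh, 12 foci, 60 leads, eikonal activations,
#' normalized integral maps and the feature matrix.  Deterministic for a
#' fixed seed.
#'
#' @param seed discretization seed (default 7).
#' @param model optional shared [membrane_model()] (to reuse its calibration
#'   cache).
#' @return list: `mesh`, `cond`, `catalog`, `leads`, `model`, `maps`,
#'   `features`, `lats`.
#' @export
make_fixture <- function(seed = 7, model = membrane_model()) {
  mesh <- assign_fibers_and_regions(build_biatrial_mesh(fixture_geometry_params(seed)))
  cond <- build_conductivity(mesh)
  catalog <- place_foci(mesh, fixture_foci_layout())
  leads <- build_torso_leads(torso_params(rows = 6, cols = 5,
                                          z_range = c(-150, 150),
                                          x_range = c(-110, 110)), mesh)
  sim <- simulate_all_foci(mesh, cond, model, catalog, leads, mode = "eikonal")
  list(mesh = mesh, cond = cond, catalog = catalog, leads = leads,
       model = model, maps = sim$maps, features = sim$features,
       lats = sim$lats)
}

#' Import externally computed BSPMs into the learning stages
#'
#' @param bspm_files character vector of per-focus BSPM CSV files (as written
#'   by [write_bspm_csv()]); file names (without extension) are the focus ids.
#' @param catalog_file catalog CSV (see [write_catalog_csv()]).
#' @return a `feature_matrix` (rows realigned to catalog order).
#' @export
import_external <- function(bspm_files, catalog_file) {
  cat_df <- read_catalog_csv(catalog_file)
  ids <- sub("\\.csv$", "", basename(bspm_files))
  if (!setequal(ids, cat_df$id))
    schema_error("BSPM files do not match the catalog ids")
  ref_labels <- NULL
  maps <- list()
  for (f in bspm_files) {
    id <- sub("\\.csv$", "", basename(f))
    b <- read_bspm_csv(f)
    if (is.null(ref_labels)) ref_labels <- b$labels
    if (!identical(b$labels, ref_labels))
      schema_error(paste("lead set mismatch in", basename(f)))
    fid <- structure(list(onset = min(b$times), offset = max(b$times)),
                     class = "fiducials")
    maps[[id]] <- pwave_integral(b, fid, focus = id)
  }
  maps <- maps[cat_df$id]
  maps <- normalize_set(maps)
  X <- t(vapply(maps, function(m) m$normalized, numeric(length(ref_labels))))
  structure(list(X = X, ids = cat_df$id,
                 centers = as.matrix(cat_df[, c("x", "y", "z")]),
                 atrium = cat_df$atrium),
            class = "feature_matrix")
}
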