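# Shared, lazily built fixtures.  Everything is generated in code at test
# time; the heavier objects are cached for the session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

get_model <- function() memo("model", function() membrane_model())

get_default_mesh <- function() memo("default_mesh", function() {
  assign_fibers_and_regions(build_biatrial_mesh(geometry_params()))
})

get_default_cond <- function() memo("default_cond", function() {
  build_conductivity(get_default_mesh())
})

get_fixture <- function() memo("fixture", function() {
  make_fixture(seed = 7, model = get_model())
})

## Small flat square with a point source in the middle (eikonal fixtures).
get_square <- function() memo("square", function() {
  sq <- strip_mesh(length_mm = 40, width_mm = 40, dx = 1.0)
  ctr <- which.min(rowSums(sweep(sq$nodes, 2, c(20, 20, 0))^2))
  list(mesh = sq, center = ctr)
})

iso_table <- function(s) {
  data.frame(region = "RA_WALL", sigma_l = s, sigma_t = s,
             sigma_i_l = 2 * s, sigma_i_t = 2 * s)
}

## Tiny synthetic bspm object.
toy_bspm <- function(Ve, times = seq_len(ncol(Ve)) - 1) {
  structure(list(Ve = Ve, times = times,
                 labels = paste0("L", seq_len(nrow(Ve))),
                 reference = "none", torso_sigma = 0.002, stim_time = times[1]),
            class = "bspm")
}

toy_fiducials <- function(onset, offset) {
  structure(list(onset = onset, offset = offset), class = "fiducials")
}

## Numeric ellipsoid surface area by dense spherical sampling.
ellipsoid_area_numeric <- function(semi, n = 400) {
  a <- semi[1]; b <- semi[2]; c <- semi[3]
  th <- seq(0, pi, length.out = n + 1)       # polar
  ph <- seq(0, 2 * pi, length.out = 2 * n + 1)
  thm <- (th[-1] + th[-length(th)]) / 2
  phm <- (ph[-1] + ph[-length(ph)]) / 2
  dth <- diff(th)[1]; dph <- diff(ph)[1]
  ## |r_theta x r_phi| for x = a sin t cos p, y = b sin t sin p, z = c cos t
  st <- sin(thm); ct <- cos(thm)
  total <- 0
  for (i in seq_along(thm)) {
    cp <- cos(phm); sp <- sin(phm)
    ex <- b * c * st[i]^2 * cp
    ey <- a * c * st[i]^2 * sp
    ez <- a * b * st[i] * ct[i]
    total <- total + sum(sqrt(ex^2 + ey^2 + ez^2)) * dth * dph
  }
  total
}

## Default 58-focus pipeline run shared by the acceptance and taxonomy tests.
get_default_run <- function() memo("default_run", function() {
  model <- get_model()
  mesh <- get_default_mesh()
  cond <- get_default_cond()
  catalog <- place_foci(mesh)
  leads <- build_torso_leads(torso_params(), mesh)
  sim <- simulate_all_foci(mesh, cond, model, catalog, leads, mode = "eikonal")
  sweep <- sweep_k(sim$features, k_range = 2:5, algorithm = "kmeans",
                   cluster_seed = 0, cv_seed = 0, n_folds = 4)
  list(sim = sim, sweep = sweep, catalog = catalog, leads = leads, mesh = mesh)
})

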