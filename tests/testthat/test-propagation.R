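test_that("membrane model rests at rest and MV variant hits 170 ms APD90", {
  model <- get_model()
  expect_lt(resting_derivative(model), 1e-6)
  expect_equal(single_cell_apd(model, "MV_RING", BCL = 500), 170,
               tolerance = 2 / 170)
  ## zero-amplitude stimulus elicits no upstroke
  expect_error(single_cell_apd(model, "MV_RING", stim_amp = 0),
               class = "bspim_stimulus_error")
})

test_that("MV variant attains the minimum APD90 over all variants", {
  model <- get_model()
  apds <- vapply(names(default_apd_targets()), function(r)
    single_cell_apd(model, r, n_beats = 3), numeric(1))
  expect_identical(names(which.min(apds)), "MV_RING")
  ## calibration hits each target within 2 ms
  expect_lt(max(abs(apds - default_apd_targets()[names(apds)])), 2)
})

test_that("monodomain respects resting equilibrium and diffusion conservation", {
  model <- get_model()
  strip <- strip_mesh(length_mm = 6, width_mm = 2, dx = 0.5)
  cond <- build_conductivity(strip, iso_table(0.003))
  ## no stimulus: stays at the diastolic state
  cat_df <- data.frame(id = "SAN", center_node = 1L, radius = 1,
                       atrium = "RA", region = "RA_WALL")
  attr(cat_df, "patches") <- list(integer(0))
  class(cat_df) <- c("foci_catalog", "data.frame")
  proto <- stimulus_protocol(n_beats = 0, focus = "SAN", amplitude = 0,
                             record_window = 50)
  tr <- solve_monodomain(strip, cond, model, proto, cat_df)
  expect_lt(max(abs(tr$V - model$V_rest)), 1e-3)
  ## pure diffusion (I_ion frozen) conserves the lumped-mass mean of V
  sys <- assemble_monodomain(strip, cond)
  v <- with_seed(2, runif(nrow(strip$nodes)))
  A <- Matrix::Diagonal(x = sys$M) + 0.05 * sys$K
  ch <- Matrix::Cholesky(A, LDL = FALSE)
  m0 <- sum(sys$M * v)
  for (i in 1:100) v <- as.numeric(Matrix::solve(ch, sys$M * v, system = "A"))
  drift <- abs(sum(sys$M * v) - m0) / (100 * 0.05)
  expect_lt(drift / sum(sys$M), 1e-8)   # mV/ms drift of the mean
})

test_that("cable conduction velocity matches the refined reference and sqrt(D) law", {
  ## Richardson-extrapolated reference computed offline from dx = 0.1 and
  ## dx = 0.05 runs of this same solver: 0.592 mm/ms at sigma = 0.003.
  model <- get_model()
  strip <- strip_mesh(length_mm = 20, width_mm = 1, dx = 0.2)
  cv <- strip_conduction_velocity(strip, build_conductivity(strip, iso_table(0.003)),
                                  model)
  expect_equal(cv, 0.592, tolerance = 0.05)
  cv4 <- strip_conduction_velocity(strip, build_conductivity(strip, iso_table(0.012)),
                                   model)
  expect_equal(cv4 / cv, 2, tolerance = 0.05)
  ## dt beyond the membrane stability limit is rejected
  cat_df <- data.frame(id = "SAN", center_node = 1L, radius = 1,
                       atrium = "RA", region = "RA_WALL")
  attr(cat_df, "patches") <- list(attr(strip, "left_edge"))
  class(cat_df) <- c("foci_catalog", "data.frame")
  expect_error(
    solve_monodomain(strip, build_conductivity(strip, iso_table(0.003)), model,
                     stimulus_protocol(n_beats = 0), cat_df, dt = 1),
    class = "bspim_parameter_error")
})

test_that("compute_lat recovers constructed shifts and rejects bad thresholds", {
  model <- get_model()
  tpl <- ap_template(model, "RA_WALL")
  ## V(x, t) = template(t - a x) on a line of nodes
  a <- 2.5
  x <- seq(0, 20, by = 0.5)
  times <- seq(0, 150, by = 1)
  V <- t(vapply(x, function(xi) {
    stats::approx(tpl$t, tpl$V, xout = times - a * xi,
                  yleft = model$V_rest, yright = model$V_rest)$y
  }, numeric(length(times))))
  tr <- structure(list(V = V, times = times, stim_time = 0, model = model),
                  class = "voltage_trace")
  lm_ <- compute_lat(tr, threshold = -40)
  fit <- stats::coef(stats::lm(lm_$lat ~ x))
  expect_equal(unname(fit[2]), a, tolerance = 1e-3)
  expect_lt(max(abs(lm_$lat - (lm_$lat[1] + a * x))), 1)  # <= 1 output step
  ## threshold below rest is undefined
  expect_error(compute_lat(tr, threshold = -90),
               class = "bspim_parameter_error")
  ## monotone along the cable
  expect_true(all(diff(lm_$lat) > 0))
})

test_that("eikonal matches closed-form distance fields", {
  sqf <- get_square()
  cond <- build_conductivity(sqf$mesh, iso_table(0.003))
  lm1 <- solve_eikonal(sqf$mesh, cond, sqf$center)
  v <- default_eikonal_calibration()$v_ref
  d <- sqrt(colSums((t(sqf$mesh$nodes) - sqf$mesh$nodes[sqf$center, ])^2))
  err <- abs(lm1$lat - d / v) / pmax(d / v, 1e-9)
  expect_lte(max(err[d > 3]), 0.02)
  ## anisotropic 4:1 conductivity: elliptic level sets with 2:1 axis ratio
  cond4 <- build_conductivity(sqf$mesh, data.frame(
    region = "RA_WALL", sigma_l = 0.012, sigma_t = 0.003,
    sigma_i_l = 0.024, sigma_i_t = 0.006))
  lm2 <- solve_eikonal(sqf$mesh, cond4, sqf$center)
  nx <- which.min(rowSums(sweep(sqf$mesh$nodes, 2, c(35, 20, 0))^2))
  ny <- which.min(rowSums(sweep(sqf$mesh$nodes, 2, c(20, 35, 0))^2))
  expect_equal(lm2$lat[ny] / lm2$lat[nx], 2, tolerance = 0.05)
})

test_that("eikonal and monodomain LATs agree on the fixture", {
  fx <- get_fixture()
  id <- "R2"
  patch <- attr(fx$catalog, "patches")[[match(id, fx$catalog$id)]]
  lme <- solve_eikonal(fx$mesh, fx$cond, patch)
  tr <- solve_monodomain(fx$mesh, fx$cond, fx$model,
                         stimulus_protocol(n_beats = 0, focus = id), fx$catalog)
  lmm <- compute_lat(tr)
  ok <- is.finite(lme$lat) & is.finite(lmm$lat)
  expect_gt(mean(ok), 0.99)
  expect_gte(stats::cor(lme$lat[ok], lmm$lat[ok]), 0.95)
})

test_that("lat_to_voltage round-trips and honors the regional APD", {
  fx <- get_fixture()
  model <- fx$model
  n <- nrow(fx$mesh$nodes)
  lm0 <- structure(list(lat = with_seed(4, runif(n, 0, 80)),
                        threshold = "eikonal", stim_time = 0),
                   class = "lat_map")
  tr <- lat_to_voltage(lm0, fx$mesh, model, times = seq(0, 320, by = 1))
  lm1 <- compute_lat(tr)
  expect_lt(max(abs(lm1$lat - lm0$lat)), 1)  # within one output step
  ## lat == 0 everywhere: all nodes share one waveform per region
  lmz <- structure(list(lat = rep(0, n), threshold = "eikonal", stim_time = 0),
                   class = "lat_map")
  dt_s <- 0.25
  trz <- lat_to_voltage(lmz, fx$mesh, model, times = seq(0, 300, by = dt_s))
  reg <- bspim:::node_regions(fx$mesh)
  nd <- which(reg == "MV_RING")
  expect_lt(max(abs(sweep(trz$V[nd, ], 2, trz$V[nd[1], ]))), 1e-9)
  ## MV-region node APD90 ~= 170 ms
  v <- trz$V[nd[1], ]
  vmax <- max(v); v90 <- vmax - 0.9 * (vmax - model$V_rest)
  iup <- which.max(diff(v))
  idn <- which(seq_along(v) > which.max(v) & v <= v90)[1]
  expect_equal((idn - iup) * dt_s, 170, tolerance = 2 / 170)
})

test_that("full capture and interatrial routing hold for the fixture catalog", {
  fx <- get_fixture()
  su <- eikonal_setup(fx$mesh, fx$cond)
  conn_nodes <- unique(as.vector(
    fx$mesh$triangles[fx$mesh$region %in% interatrial_labels(), ]))
  for (i in seq_len(nrow(fx$catalog))) {
    lm_ <- solve_eikonal(fx$mesh, fx$cond, attr(fx$catalog, "patches")[[i]],
                         setup = su)
    expect_true(all(is.finite(lm_$lat)))            # full capture
    expect_lt(max(lm_$lat), 350)                    # inside the record window
    if (fx$catalog$atrium[i] == "RA") {
      ## wavefront-path audit: the earliest LA activation is not earlier than
      ## the earliest activation of an interatrial connection node
      la_nodes <- which(fx$mesh$atrium == "LA")
      t_gate <- min(lm_$lat[intersect(conn_nodes, seq_along(lm_$lat))])
      expect_gte(min(lm_$lat[setdiff(la_nodes, conn_nodes)]), t_gate - 1e-6)
    }
  }
})
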