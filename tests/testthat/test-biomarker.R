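test_that("fiducials follow the activation map", {
  lm0 <- structure(list(lat = rep(0, 5), threshold = "eikonal", stim_time = 100),
                   class = "lat_map")
  f0 <- detect_fiducials(lm0)
  expect_identical(f0$offset, f0$onset)
  lm1 <- structure(list(lat = c(0, 40, 80), threshold = "eikonal", stim_time = 10),
                   class = "lat_map")
  f1 <- detect_fiducials(lm1)
  expect_identical(f1$onset, 10)
  expect_identical(f1$offset, 90)
  lmi <- structure(list(lat = c(0, Inf), threshold = "eikonal", stim_time = 0),
                   class = "lat_map")
  expect_error(detect_fiducials(lmi), class = "bspim_validation_error")
})

test_that("eikonal strip traversal time matches distance over speed", {
  ## 50 mm strip at the calibrated reference speed
  strip <- strip_mesh(length_mm = 50, width_mm = 2, dx = 0.5)
  cond <- build_conductivity(strip, iso_table(0.003))
  src <- which(strip$nodes[, 1] == 0)
  lm_ <- solve_eikonal(strip, cond, src)
  fid <- detect_fiducials(lm_, stim_time = 0)
  v <- default_eikonal_calibration()$v_ref
  expect_equal(fid$offset - fid$onset, 50 / v, tolerance = 0.02)
})

test_that("P-wave integral: trapezoid exactness and analytic sine check", {
  ## constant signal: c * window length, exactly
  Ve <- rbind(rep(2.5, 101), rep(0, 101))
  b <- toy_bspm(Ve, times = 0:100)
  fid <- toy_fiducials(0, 100)
  m <- pwave_integral(b, fid)
  expect_equal(m$values, c(250, 0), tolerance = 1e-12)
  ## zero signal
  expect_equal(pwave_integral(toy_bspm(matrix(0, 3, 50)), toy_fiducials(0, 49))$values,
               rep(0, 3))
  ## sine half-arch: integral 2 d / pi within 0.1%
  d <- 100
  Ve2 <- matrix(sin(pi * (0:d) / d), 1)
  m2 <- pwave_integral(toy_bspm(Ve2, times = 0:d), toy_fiducials(0, d))
  expect_equal(m2$values, 2 * d / pi, tolerance = 1e-3)
  ## window outside the trace
  expect_error(pwave_integral(b, toy_fiducials(0, 500)),
               class = "bspim_range_error")
  ## linearity
  A <- with_seed(1, matrix(rnorm(5 * 60), 5)); B <- with_seed(2, matrix(rnorm(5 * 60), 5))
  fid3 <- toy_fiducials(5, 50)
  ia <- pwave_integral(toy_bspm(A, 0:59), fid3)$values
  ib <- pwave_integral(toy_bspm(B, 0:59), fid3)$values
  iab <- pwave_integral(toy_bspm(2 * A - 3 * B, 0:59), fid3)$values
  expect_equal(iab, 2 * ia - 3 * ib, tolerance = 1e-10)
})

test_that("RMS, extrema and product maps behave as defined", {
  fid <- toy_fiducials(0, 49)
  cst <- toy_bspm(matrix(-1.5, 2, 50))
  expect_equal(rms_map(cst, fid), c(1.5, 1.5))
  ex <- extrema_maps(cst, fid)
  expect_equal(ex$max, ex$min)
  ## sign flip: RMS unchanged, extrema swap
  R <- with_seed(8, matrix(rnorm(4 * 50), 4))
  b1 <- toy_bspm(R); b2 <- toy_bspm(-R)
  expect_equal(rms_map(b1, fid), rms_map(b2, fid), tolerance = 1e-12)
  e1 <- extrema_maps(b1, fid); e2 <- extrema_maps(b2, fid)
  expect_equal(e1$max, -e2$min, tolerance = 1e-12)
  ## Jensen: RMS^2 >= mean^2 per lead
  expect_true(all(rms_map(b1, fid)^2 >= rowMeans(R)^2 - 1e-12))
  ## product map is the elementwise product
  im <- pwave_integral(b1, fid)
  expect_equal(product_map(rms_map(b1, fid), im),
               rms_map(b1, fid) * im$values)
  ## suite agrees with a direct-summation oracle on a 5-lead, 10-sample toy
  S <- with_seed(5, matrix(rnorm(50), 5))
  bs <- toy_bspm(S, times = 0:9)
  fid10 <- toy_fiducials(0, 9)
  suite <- biomarker_suite(bs, fid10)
  for (l in 1:5) {
    trap <- sum((S[l, -1] + S[l, -10]) / 2)
    expect_equal(suite$integral$values[l], trap, tolerance = 1e-12)
    expect_equal(suite$rms[l], sqrt(mean(S[l, ]^2)), tolerance = 1e-12)
    expect_equal(suite$max[l], max(S[l, ]))
    expect_equal(suite$min[l], min(S[l, ]))
    expect_equal(suite$rms_x_integral[l], suite$rms[l] * trap, tolerance = 1e-12)
  }
})

test_that("global-range normalization scales, preserves order, is idempotent", {
  m1 <- bspim:::new_bspim_map(c(-2, 1), paste0("L", 1:2))
  n1 <- normalize_set(list(m1))
  expect_equal(n1[[1]]$normalized, c(-1, 0.5))
  m2 <- bspim:::new_bspim_map(1, "L1")
  m3 <- bspim:::new_bspim_map(4, "L1")
  nn <- normalize_set(list(m2, m3))
  expect_equal(nn[[1]]$normalized, 0.25)
  expect_equal(nn[[2]]$normalized, 1)
  ## order preserved within each map
  set.seed(12)
  maps <- lapply(1:5, function(i) bspim:::new_bspim_map(rnorm(30), paste0("L", 1:30)))
  nm <- normalize_set(maps)
  for (i in 1:5)
    expect_identical(order(nm[[i]]$normalized), order(maps[[i]]$values))
  ## idempotence
  maps2 <- lapply(nm, function(m) { m$values <- m$normalized; m })
  nm2 <- normalize_set(maps2)
  for (i in 1:5)
    expect_equal(nm2[[i]]$normalized, nm[[i]]$normalized, tolerance = 1e-12)
  ## all-zero set errors
  z <- bspim:::new_bspim_map(rep(0, 3), paste0("L", 1:3))
  expect_error(normalize_set(list(z)), class = "bspim_normalization_error")
})

test_that("dipole axis classification and antisymmetry", {
  leads <- structure(data.frame(label = c("up", "down", "left", "right"),
                                x = c(0, 0, 60, -60), y = c(-80, -80, -40, -40),
                                z = c(60, -60, 0, 0), side = "front"),
                     class = c("lead_set", "data.frame"))
  m <- bspim:::new_bspim_map(c(1, -1, 0, 0), leads$label)
  ax <- dipole_axis(m, leads)
  expect_identical(ax$class, "upward")
  mneg <- bspim:::new_bspim_map(-c(1, -1, 0, 0), leads$label)
  axn <- dipole_axis(mneg, leads)
  expect_identical(axn$class, "downward")
  expect_equal(axn$direction, -ax$direction)
  flat <- bspim:::new_bspim_map(rep(1, 4), leads$label)
  expect_error(dipole_axis(flat, leads), class = "bspim_degenerate_axis_error")
})

test_that("fixture maps are non-degenerate: both signs present", {
  fx <- get_fixture()
  signs_ok <- vapply(fx$maps, function(m)
    any(m$values > 0) && any(m$values < 0), logical(1))
  expect_true(all(signs_ok))
})
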