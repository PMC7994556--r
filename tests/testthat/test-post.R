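# synthetic flow-field wrapper for testing the shear invariant on constructed
# velocity fields
synthetic_flow <- function(grid, ufun, vfun, fluid = blood_newtonian()) {
  u <- matrix(ufun(as.vector(grid$X), as.vector(grid$Y)),
              grid$nx + 1, grid$ny + 1)
  v <- matrix(vfun(as.vector(grid$X), as.vector(grid$Y)),
              grid$nx + 1, grid$ny + 1)
  structure(list(u = u, v = v, grid = grid, fluid = fluid,
                 mu_field = matrix(fluid$mu, grid$nx + 1, grid$ny + 1),
                 converged = TRUE, U_ref = max(abs(u), 1e-9)),
            class = "flow_field")
}

test_that("shear invariant recovers |du/dy| for plane shear and vanishes for rigid motions", {
  g0 <- stenosis_geometry(S = 0, alpha = 85)
  gr <- generate_grid(g0, nx = 16, ny = 16, cluster = 0, eta_cluster = 0)
  shear <- synthetic_flow(gr, function(x, y) 500 * y, function(x, y) 0 * x)
  m <- shear_rate_field(shear)
  expect_equal(max(abs(m$gamma - 500)), 0, tolerance = 1e-6)
  translation <- synthetic_flow(gr, function(x, y) 0.3 + 0 * x, function(x, y) 0.1 + 0 * x)
  expect_lt(max(shear_rate_field(translation)$gamma), 1e-8)
  rotation <- synthetic_flow(gr, function(x, y) -50 * (y - 5e-5),
                             function(x, y) 50 * (x - 0))
  expect_lt(max(shear_rate_field(rotation)$gamma), 1e-5)
})

test_that("straight-channel WSS is uniform and equals mu * gamma0", {
  pc <- poiseuille_flow(ny = 64)
  map <- shear_rate_field(pc$flow)
  tau_expect <- 0.00345 * 1000
  sel <- 2:pc$grid$nx # away from the inlet/outlet closure columns
  expect_true(all(abs(map$tau_bottom$tau_Pa[sel] - tau_expect) / tau_expect < 0.01))
  expect_true(all(abs(map$tau_top$tau_Pa[sel] - tau_expect) / tau_expect < 0.01))
  # dyn/cm2 report convention
  expect_equal(map$tau_bottom$tau_dyn_cm2, 10 * map$tau_bottom$tau_Pa)
})

test_that("tau_max lies inside the stenotic region and doubles with the flow rate", {
  pk <- stenosis_peaks()
  g <- pk$flow$geom
  expect_lt(abs(pk$map$tau_max$x), g$footprint / 2)
  pk2 <- stenosis_peaks(gamma0 = 2000)
  expect_equal(pk2$map$tau_max$value / pk$map$tau_max$value, 2, tolerance = 0.03)
})

test_that("Newtonian wall stress equals viscosity times wall shear rate pointwise", {
  pk <- stenosis_peaks()
  map <- pk$map
  expect_equal(map$tau_bottom$tau_Pa, 0.00345 * map$tau_bottom$gamma_wall)
})

test_that("streamlines behave: straight channel horizontal, concentric centerline straight", {
  pc <- poiseuille_flow(ny = 64)
  tr <- trace_streamline(pc$flow, c(-180e-6, 30e-6))
  expect_lt(max(abs(tr$y_um - 30)), 1e-3 * 100)
  expect_true(all(tr$speed > 0))
  cc <- stenosis_flow(placement = "concentric", nx = 128, ny = 32)
  trc <- trace_streamline(cc$flow, c(-350e-6, 50e-6))
  expect_lt(max(abs(trc$y_um - 50)), 1e-3 * 100)
  # speed never vanishes before the outlet
  expect_true(all(trc$speed > 1e-12 * cc$flow$U_ref))
})

test_that("streamline tracer rejects bad seeds", {
  pc <- poiseuille_flow(ny = 64)
  expect_error(trace_streamline(pc$flow, c(-180e-6, 150e-6)), "outside")
  # a seed on the wall itself has zero interpolated velocity
  expect_error(trace_streamline(pc$flow, c(-180e-6, 0)), "stagnant")
})

test_that("platelet trajectory hits the clearance and peaks at the apex", {
  pk <- stenosis_peaks()
  pr <- pk$profile
  expect_lt(abs(pr$clearance_um - 1), 0.0501)
  expect_lt(abs(pr$gamma_max_x_um), 5)
  # profile gamma_max cannot exceed the field-wide maximum
  expect_lte(pr$gamma_max, pk$map$gamma_max_field$value * (1 + 1e-9))
  # gradient integrates back to the sampled shear history
  n <- length(pr$x_um)
  recon <- pr$gamma_s[1] + cumsum(c(0, (pr$gamma_prime[-1] + pr$gamma_prime[-n]) / 2 *
                                      diff(pr$x_um)))
  expect_lt(max(abs(recon - pr$gamma_s)) / diff(range(pr$gamma_s)), 0.01)
})

test_that("straight channel has zero shear-rate gradient along the trajectory", {
  pc <- poiseuille_flow(ny = 64)
  map <- shear_rate_field(pc$flow)
  tr <- trace_streamline(pc$flow, c(-180e-6, 10e-6))
  # gamma along a horizontal line is constant => gradient ~ 0
  sel <- abs(tr$x_um) <= 100
  expect_lt(diff(range(tr$y_um[sel])), 1e-3)
})

test_that("peak summary collects non-negative peaks consistently", {
  pk <- stenosis_peaks()
  rec <- peak_summary(pk$profile, pk$map)
  expect_true(all(rec[, c("gamma_max_s_inv", "gamma_prime_max_um_inv_s_inv",
                          "tau_max_Pa")] >= 0))
  expect_equal(rec$tau_max_dyn_cm2, 10 * rec$tau_max_Pa)
  expect_equal(rec$gamma_max_s_inv, pk$profile$gamma_max)
})
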