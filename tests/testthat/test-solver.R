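test_that("solver reproduces plane Poiseuille flow within 1% at ny = 64", {
  pc <- poiseuille_flow(ny = 64)
  fl <- pc$flow; gr <- pc$grid
  u_exact <- pc$case$closed_form$u(gr$Y)
  expect_lt(max(abs(fl$u - u_exact)) / max(u_exact), 0.01)
  expect_lt(max(abs(fl$v)) / max(u_exact), 0.01)
  expect_true(fl$converged)
})

test_that("mass flux through every axial station equals the inlet flux to 1e-8", {
  pc <- poiseuille_flow(ny = 64)
  fl <- pc$flow
  expect_lt(fl$mass_imbalance, 1e-8)
  station_flux <- fl$psi[, ncol(fl$psi)] - fl$psi[, 1]
  expect_true(all(abs(station_flux - fl$q2d) / fl$q2d < 1e-8))
  # and on a contorted geometry too
  st <- stenosis_flow()
  expect_lt(st$flow$mass_imbalance, 1e-8)
})

test_that("no-slip wall velocities vanish", {
  st <- stenosis_flow()
  fl <- st$flow
  nj <- ncol(fl$u)
  wall_speed <- sqrt(fl$u[, c(1, nj)]^2 + fl$v[, c(1, nj)]^2)
  expect_lt(max(wall_speed), 1e-12 * fl$U_ref)
})

test_that("concentric solution is mirror symmetric about the centerline", {
  cs <- stenosis_flow(placement = "concentric", nx = 128, ny = 32)
  fl <- cs$flow
  nj <- ncol(fl$u)
  asym_u <- max(abs(fl$u - fl$u[, nj:1])) / fl$U_ref
  asym_v <- max(abs(fl$v + fl$v[, nj:1])) / fl$U_ref
  expect_lt(asym_u, 1e-6)
  expect_lt(asym_v, 1e-6)
})

test_that("creeping-flow linearity: scaling gamma0 by 20 scales the shear observables by ~20", {
  lo <- stenosis_peaks(gamma0 = 150)
  hi <- stenosis_peaks(gamma0 = 3000)
  expect_equal(hi$profile$gamma_max / lo$profile$gamma_max, 20, tolerance = 0.03)
  expect_equal(hi$map$tau_max$value / lo$map$tau_max$value, 20, tolerance = 0.03)
  expect_equal(hi$flow$U_ref / lo$flow$U_ref, 20, tolerance = 0.03)
})

test_that("GPL and Newtonian blood give nearly identical shear fields at gamma0 = 1000", {
  newt <- stenosis_peaks(nx = 128, ny = 32)
  gpl <- stenosis_peaks(nx = 128, ny = 32, fluid = blood_gpl())
  rel <- abs(gpl$profile$gamma_max - newt$profile$gamma_max) / newt$profile$gamma_max
  expect_lt(rel, 0.05)
})

test_that("solver rejects bad inputs and reports non-convergence with history", {
  g <- stenosis_geometry(S = 0.8, alpha = 85)
  gr <- generate_grid(g, 64, 16)
  expect_error(solve_flow(g, blood_newtonian(), -5, gr), "positive")
  g97 <- stenosis_geometry(S = 0.975, alpha = 85)
  gr97 <- generate_grid(g97, 64, 16)
  expect_error(solve_flow(g97, blood_newtonian(), 1000, gr97), "refused")
  err <- tryCatch(
    solve_flow(g, blood_newtonian(), 1000, gr,
               solver_config(tol = 1e-14, max_iter = 2)),
    error = function(e) e)
  expect_s3_class(err, "stenoflow_no_convergence")
  expect_true(is.data.frame(err$residual_history))
  expect_equal(nrow(err$residual_history), 2)
})

test_that("solver configuration validates its inputs", {
  expect_error(solver_config(tol = -1), "tol")
  expect_error(solver_config(relax_u = 0), "relaxation")
  expect_error(solver_config(convection_scheme = "upwind"), "central")
})

test_that("recovered pressure drops across the contraction", {
  st <- stenosis_flow()
  p_station <- rowMeans(st$flow$P)
  x <- st$grid$X[, 1] * 1e6
  p_up <- p_station[which.min(abs(x + 350))]
  p_pre <- p_station[which.min(abs(x + 50))]
  p_post <- p_station[which.min(abs(x - 50))]
  p_down <- p_station[which.min(abs(x - 350))]
  expect_gt(p_up, p_pre)        # entrance run loss
  expect_gt(p_pre, p_post)      # the hump carries the dominant drop
  expect_gt(p_post, p_down)     # exit run loss
})
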