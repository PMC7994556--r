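test_that("Poiseuille fixture carries a consistent closed form", {
  case <- make_poiseuille_case(Y0 = 100, gamma0 = 1500)
  w <- 100e-6
  cf <- case$closed_form
  # wall shear of the closed form equals the requested gamma0
  eps <- 1e-9
  expect_equal((cf$u(eps) - cf$u(0)) / eps, 1500, tolerance = 1e-4)
  # analytic flux equals q
  y <- seq(0, w, length.out = 20001)
  flux <- sum((cf$u(y)[-1] + cf$u(y)[-length(y)]) / 2 * diff(y))
  expect_equal(flux, cf$q, tolerance = 1e-6)
})

test_that("randomized suite is reproducible and valid (see geometry tests for 500-draw audit)", {
  a <- random_geometry_suite(25, seed = 42)
  b <- random_geometry_suite(25, seed = 42)
  expect_identical(vapply(a, `[[`, numeric(1), "S"),
                   vapply(b, `[[`, numeric(1), "S"))
  expect_error(random_geometry_suite(0), "positive")
})

test_that("grid convergence on the Poiseuille oracle shows second-order behavior", {
  conv <- cached("conv_pois", mesh_sensitivity(make_poiseuille_case(),
                                               levels = 3, base_grid = c(16, 16)))
  expect_true(conv$monotone)
  expect_true(conv$shrinking_differences)
  expect_gte(conv$observed_order, 1.5)
  expect_lte(conv$observed_order, 2.5)
  # extrapolated peak velocity matches the closed form to 0.2%
  u_max_exact <- 1000 * (100 * 1e-6) / 4
  expect_equal(conv$richardson, u_max_exact, tolerance = 2e-3)
  # the wall shear itself is nodally exact for this discretization
  pc <- poiseuille_flow(ny = 64)
  m <- shear_rate_field(pc$flow)
  expect_equal(mean(m$tau_bottom$gamma_wall[2:32]), 1000, tolerance = 2e-3)
})

test_that("mesh sensitivity rejects too few levels and flags non-asymptotic sequences", {
  expect_error(mesh_sensitivity(levels = 2), "at least 3")
  rep_fake <- structure(list(nx = c(8, 16, 32), ny = c(8, 16, 32),
                             observable = c(1, 3, 2), refinement_ratio = 2,
                             monotone = FALSE, shrinking_differences = FALSE,
                             asymptotic = FALSE, observed_order = NA_real_,
                             richardson = NA_real_, gci = NA_real_,
                             case = "synthetic"),
                        class = "convergence_report")
  expect_output(print(rep_fake), "non-asymptotic")
})

test_that("verification report runs end to end and passes its own checks", {
  rep <- cached("verif", verification_report(outdir = NULL, n_random = 50))
  expect_lt(rep$poiseuille_velocity_rel_err, 0.01)
  expect_lt(rep$poiseuille_wall_shear_rel_err, 0.01)
  expect_lt(rep$mass_imbalance, 1e-8)
  expect_true(rep$random_suite_throat_identity)
})
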