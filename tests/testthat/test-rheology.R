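test_that("GPL apparent viscosity matches its closed form at reference shear rates", {
  blood <- blood_gpl()
  # high-shear plateau: the shear-thinning terms have decayed by 1000 1/s
  expect_equal(apparent_viscosity(blood, 1000), 0.00345, tolerance = 1e-4)
  # low-shear evaluation, frozen from an independent evaluation of K and n
  p <- blood$params
  expect_equal(gpl_K <- stenoflow:::gpl_K(1, p), 0.241071, tolerance = 1e-5)
  expect_equal(stenoflow:::gpl_n(1, p), 0.558329, tolerance = 1e-5)
  expect_equal(apparent_viscosity(blood, 1), 0.241071, tolerance = 1e-5)
})

test_that("GPL limits: Newtonian plateau at high shear, yield-like thickening at low shear", {
  p <- blood_gpl()$params
  expect_equal(stenoflow:::gpl_K(1e6, p), 0.00345, tolerance = 1e-3)
  expect_equal(stenoflow:::gpl_n(1e6, p), 1.0, tolerance = 1e-3)
  expect_equal(apparent_viscosity(blood_gpl(), 1e6), 0.00345, tolerance = 1e-3)
  expect_equal(stenoflow:::gpl_K(1e-6, p), 0.25345, tolerance = 1e-3)
  expect_equal(stenoflow:::gpl_n(1e-6, p), 0.55, tolerance = 1e-3)
})

test_that("GPL viscosity is shear-thinning (monotone non-increasing) over a wide log grid", {
  g <- 10^seq(-3, 6, length.out = 400)
  mu <- apparent_viscosity(blood_gpl(), g)
  expect_true(all(diff(mu) <= 1e-15))
  expect_true(all(is.finite(mu) & mu > 0))
})

test_that("Newtonian fluids return their tabulated constant viscosity", {
  g <- c(0, 1, 100, 5000)
  expect_equal(apparent_viscosity(water(), g), rep(0.001003, 4))
  expect_equal(apparent_viscosity(blood_newtonian(), g), rep(0.00345, 4))
  expect_equal(water()$rho, 998)
  expect_equal(blood_newtonian()$rho, 1060)
})

test_that("viscosity benchmark table has the expected shape and model behaviors", {
  tab <- viscosity_benchmark()
  expect_equal(tab$gamma_s_inv, seq(50, 1050, by = 10))
  expect_equal(ncol(tab), 6) # gamma + 5 models
  gpl <- tab[["blood (GPL)"]]
  expect_true(all(diff(gpl) <= 1e-15))
  plateau <- tab$gamma_s_inv >= 500
  expect_true(all(abs(gpl[plateau] - 0.00345) / 0.00345 < 0.05))
  expect_true(all(tab[["blood (Newtonian)"]] == 0.00345))
  pl <- tab[["blood (Power-Law)"]]
  expect_true(all(diff(pl) < 0)) # no plateau: strictly decreasing
})

test_that("invalid rheology inputs are rejected", {
  expect_error(fluid_model("x", rho = -1, law = "newtonian", mu = 1), "rho")
  expect_error(fluid_model("x", rho = 1000, law = "newtonian"), "mu")
  expect_error(fluid_model("x", rho = 1000, law = "nope"), "arg")
  expect_error(apparent_viscosity(blood_gpl(), -5), "non-negative")
  expect_error(viscosity_benchmark(list()), "at least one")
  expect_error(viscosity_benchmark(gamma = c(5, 1)), "increasing")
})
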