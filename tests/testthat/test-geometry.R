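test_that("straight channel and throat-width identities hold", {
  g0 <- stenosis_geometry(S = 0, alpha = 45)
  xs <- seq(-400, 400, length.out = 101)
  expect_equal(g0$y_bottom(xs), rep(0, 101))
  expect_equal(g0$y_top(xs), rep(100, 101))
  g8 <- stenosis_geometry(S = 0.8, alpha = 85)
  expect_equal(g8$throat, 20)
  expect_equal(g8$y_top(0) - g8$y_bottom(0), 20)
})

test_that("throat-width identity holds across a large randomized suite", {
  geoms <- random_geometry_suite(500, seed = 7)
  expect_length(geoms, 500)
  for (g in geoms) {
    xs <- c(0, seq(-g$footprint / 2 - 2, g$footprint / 2 + 2, length.out = 501))
    gap <- g$y_top(xs) - g$y_bottom(xs)
    expect_true(all(gap > 0))
    expect_lt(abs(min(gap) - g$Y0 * (1 - g$S)), 1e-9 * g$Y0)
  }
  # identical seed reproduces the identical suite
  geoms2 <- random_geometry_suite(500, seed = 7)
  expect_identical(lapply(geoms, function(g) c(g$S, g$alpha)),
                   lapply(geoms2, function(g) c(g$S, g$alpha)))
})

test_that("concentric geometry is mirror symmetric and relates to the eccentric profile", {
  gc <- stenosis_geometry(S = 0.7, alpha = 60, placement = "concentric")
  xs <- seq(-150, 150, length.out = 401)
  expect_equal(gc$y_bottom(xs) + gc$y_top(xs), rep(100, 401))
  # eccentric bottom wall = concentric bottom wall with hump height doubled
  ge <- stenosis_geometry(S = 0.7, alpha = 60, placement = "eccentric")
  gc2 <- stenosis_geometry(S = 0.35, alpha = 60, placement = "concentric")
  # same ramp angle, half height each: concentric at S/2 has the same total
  # bottom hump shape as eccentric at S only when heights match; verify via
  # the per-side constructor instead:
  hump_e <- stenoflow:::make_hump(70, 60 * pi / 180, 6)
  hump_c <- stenoflow:::make_hump(35, 60 * pi / 180, 6)
  expect_equal(ge$y_bottom(xs), hump_e$f(xs))
  expect_equal(gc$y_bottom(xs), hump_c$f(xs))
})

test_that("hump footprint shrinks monotonically as the contraction angle increases", {
  alphas <- c(30, 40, 50, 60, 70, 80, 85)
  fp <- vapply(alphas, function(a)
    stenosis_geometry(S = 0.8, alpha = a)$footprint, numeric(1))
  expect_true(all(diff(fp) < 0))
})

test_that("invalid geometries are rejected with informative errors", {
  expect_error(stenosis_geometry(S = 1, alpha = 85), "stenosis fraction")
  expect_error(stenosis_geometry(S = -0.1, alpha = 85), "stenosis fraction")
  expect_error(stenosis_geometry(S = 0.5, alpha = 0), "contraction angle")
  expect_error(stenosis_geometry(S = 0.5, alpha = 95), "contraction angle")
  expect_error(stenosis_geometry(S = 0.5, alpha = 85, Y0 = -1), "positive")
  # shallow angle + tall hump: footprint exceeds the channel: infeasible
  expect_error(stenosis_geometry(S = 0.95, alpha = 5), "infeasible")
  expect_error(stenosis_geometry(S = 0.8, alpha = 90), "vertical ramp")
})

test_that("generated grids satisfy the mesh invariants", {
  g <- stenosis_geometry(S = 0.8, alpha = 85)
  gr <- generate_grid(g, nx = 64, ny = 16)
  expect_true(all(grid_cell_areas(gr) > 0))
  # boundary nodes lie exactly on the wall profiles
  xb <- gr$X[, 1] * 1e6
  expect_equal(gr$Y[, 1] * 1e6, g$y_bottom(xb), tolerance = 1e-12)
  xt <- gr$X[, gr$ny + 1] * 1e6
  expect_equal(gr$Y[, gr$ny + 1] * 1e6, g$y_top(xt), tolerance = 1e-12)
  # doubling cell counts quadruples the cell count
  gr2 <- generate_grid(g, nx = 128, ny = 32)
  expect_equal(length(grid_cell_areas(gr2)), 4 * length(grid_cell_areas(gr)))
  expect_error(generate_grid(g, nx = 4, ny = 4), "at least 8")
})

test_that("straight-channel grid is uniform rectangular with equal cell areas", {
  g0 <- stenosis_geometry(S = 0, alpha = 85)
  gr <- generate_grid(g0, nx = 16, ny = 8, cluster = 0, eta_cluster = 0)
  areas <- grid_cell_areas(gr)
  expect_equal(max(areas) / min(areas), 1, tolerance = 1e-9)
})

test_that("severe stenosis grid resolves the throat", {
  g <- stenosis_geometry(S = 0.95, alpha = 85)
  gr <- generate_grid(g, nx = 96, ny = 24)
  # min transverse cell extent at the apex is below throat/ny and positive
  i0 <- which.min(abs(gr$X[, 1]))
  dy <- diff(gr$Y[i0, ]) * 1e6
  expect_true(all(dy > 0))
  expect_lte(min(dy), g$throat / gr$ny)
})

test_that("wall_profiles returns a tidy table over the analysis window", {
  g <- stenosis_geometry(S = 0.6, alpha = 75)
  wp <- wall_profiles(g)
  expect_named(wp, c("x_um", "y_bottom_um", "y_top_um"))
  expect_equal(range(wp$x_um), c(-100, 100))
  expect_true(all(wp$y_top_um - wp$y_bottom_um > 0))
})
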