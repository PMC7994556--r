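# small sweep reused by several tests (3 operating points, one placement,
# coarse grid: study machinery under test, not solution accuracy)
small_sweep <- function() {
  cached("sweep_g0", run_study("gamma0_sweep",
                               config = list(gamma0 = c(150, 1000, 3000),
                                             placements = "eccentric"),
                               grid = c(128, 32)))
}

test_that("bulk-shear-rate sweep is linear with fold-change anchored at one", {
  sw <- small_sweep()
  tab <- sw$table
  expect_equal(nrow(tab), 3)
  expect_equal(tab$fold_gamma_max[1], 1)
  expect_gt(sw$fit$eccentric$r_squared, 0.999)
  # ~20-fold growth over the 150 -> 3000 span
  expect_equal(tab$fold_gamma_max[3], 20, tolerance = 0.1)
  # every swept value appears exactly once per placement
  expect_equal(sort(tab$gamma0), c(150, 1000, 3000))
})

test_that("study report artifacts are deterministic", {
  sw <- small_sweep()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  study_report(sw, d1, figures = FALSE)
  study_report(sw, d2, figures = FALSE)
  f1 <- file.path(d1, "gamma0_sweep.csv"); f2 <- file.path(d2, "gamma0_sweep.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  js <- jsonlite::read_json(file.path(d1, "gamma0_sweep.json"))
  expect_equal(js$n_runs, 3)
})

test_that("fold-change column is recomputable from the peak column", {
  sw <- small_sweep()
  tab <- sw$table
  expect_equal(tab$fold_gamma_max,
               tab$gamma_max_s_inv / tab$gamma_max_s_inv[1])
})

test_that("a failing sweep member aborts with the offending value identified", {
  expect_error(
    run_study("S_sweep", config = list(S = c(0.3, 0.975), placements = "eccentric"),
              grid = c(96, 24)),
    "S = 0.975")
})

test_that("run configuration files round-trip through the YAML reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "geometry: {S: 0.6, alpha_deg: 75, placement: concentric}",
    "fluid: {name: blood_gpl}",
    "operating: {gamma0_s_inv: 600}",
    "solver: {nx: 96, ny: 24}"), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$geom$S, 0.6)
  expect_equal(cfg$geom$placement, "concentric")
  expect_equal(cfg$fluid$law, "gpl")
  expect_equal(cfg$gamma0, 600)
  expect_equal(cfg$grid_size, c(96, 24))
  # flow-rate-specified operating point inverts to gamma0
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("operating: {Q_uL_min: 12.256717}", path2)
  cfg2 <- read_run_config(path2)
  expect_equal(cfg2$gamma0, 1000, tolerance = 1e-4)
})

test_that("VTK and metadata exports write well-formed files", {
  pc <- poiseuille_flow(ny = 64)
  vtk <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(pc$flow, vtk)
  head <- readLines(vtk, n = 6)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[4], "STRUCTURED_GRID")
  expect_match(head[5], sprintf("DIMENSIONS %d %d 1", 33, 65))
  js <- withr::local_tempfile(fileext = ".json")
  write_run_metadata(pc$flow, js)
  meta <- jsonlite::read_json(js)
  expect_true(meta$solve$converged)
  expect_equal(meta$grid$nx, 32)
})
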