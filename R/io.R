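#' Read a run configuration file
#'
#' Run configurations are YAML with up to four blocks:
#'
#' ```yaml
#' geometry: {X0_um: 200, Y0_um: 100, Z0_um: 130, S: 0.8, alpha_deg: 85,
#'            placement: eccentric, fillet_um: 2}
#' fluid:    {name: blood_newtonian}        # or water / blood_gpl, or
#'                                          # {rho: 1060, law: newtonian, mu: 0.00345}
#' operating: {gamma0_s_inv: 1000}          # or Q_uL_min; f_Hz optional
#' solver:   {nx: 192, ny: 48, tol: 1.0e-7, max_iter: 50}
#' ```
#'
#' Missing keys fall back to the documented defaults.
#'
#' @param path YAML file path.
#' @return List with `geom` ([stenosis_geometry()]), `fluid`
#'   ([fluid_model()]), `gamma0`, `grid_size` and `solver`
#'   ([solver_config()]).
#' @export
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example-run.yaml",
#'                                    package = "stenoflow"))
#' cfg$geom
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gb <- cfg$geometry %||% list()
  geom <- stenosis_geometry(
    S = gb$S %||% 0.8,
    alpha = gb$alpha_deg %||% 85,
    placement = gb$placement %||% "eccentric",
    X0 = gb$X0_um %||% 200, Y0 = gb$Y0_um %||% 100, Z0 = gb$Z0_um %||% 130,
    fillet_radius = gb$fillet_um %||% 2
  )
  fb <- cfg$fluid %||% list(name = "blood_newtonian")
  fluid <- if (!is.null(fb$name)) fluid_by_name(fb$name) else
    fluid_model(fb$label %||% "custom", rho = fb$rho,
                law = fb$law %||% "newtonian", mu = fb$mu,
                params = fb$params %||% list())
  ob <- cfg$operating %||% list()
  gamma0 <- if (!is.null(ob$gamma0_s_inv)) ob$gamma0_s_inv else if
    (!is.null(ob$Q_uL_min)) {
    # invert the bench flow-rate formula at this cross-section
    ob$Q_uL_min / flow_rate(1, geom$Y0, geom$Z0)
  } else 1000
  sb <- cfg$solver %||% list()
  list(
    geom = geom, fluid = fluid, gamma0 = gamma0,
    f_Hz = ob$f_Hz %||% NULL,
    grid_size = c(sb$nx %||% 192, sb$ny %||% 48),
    solver = solver_config(tol = sb$tol %||% 1e-7,
                           max_iter = sb$max_iter %||% 50)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a flow field as a legacy-VTK structured grid
#'
#' Writes an ASCII legacy VTK file (`STRUCTURED_GRID`) with point data:
#' velocity vector (m/s), pressure (Pa), viscosity (Pa s), and shear rate
#' (1/s) if a map is supplied. Readable by ParaView and VisIt.
#'
#' @param flow a [solve_flow()] result.
#' @param path output `.vtk` path.
#' @param map optionally a [shear_rate_field()] to include the shear field.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(flow, path, map = NULL) {
  grid <- flow$grid
  ni <- grid$nx + 1; nj <- grid$ny + 1
  n <- ni * nj
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0",
     "stenoflow structured grid", "ASCII",
     "DATASET STRUCTURED_GRID",
     sprintf("DIMENSIONS %d %d 1", ni, nj),
     sprintf("POINTS %d double", n))
  pts <- cbind(as.vector(grid$X), as.vector(grid$Y), 0)
  utils::write.table(format(pts, digits = 10, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl(sprintf("POINT_DATA %d", n),
     "VECTORS velocity double")
  vel <- cbind(as.vector(flow$u), as.vector(flow$v), 0)
  utils::write.table(format(vel, digits = 10, scientific = TRUE, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  scal <- function(name, m) {
    wl(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default")
    writeLines(format(as.vector(m), digits = 10, scientific = TRUE, trim = TRUE), con)
  }
  scal("pressure", flow$P)
  scal("viscosity", flow$mu_field)
  if (!is.null(map)) scal("shear_rate", map$gamma)
  invisible(path)
}

#' Write run metadata JSON
#'
#' Records the inputs and convergence diagnostics of a solve (geometry,
#' fluid, operating point, grid, iterations, final residual, mass imbalance)
#' for provenance alongside exported fields.
#'
#' @param flow a [solve_flow()] result.
#' @param path output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_run_metadata <- function(flow, path) {
  g <- flow$geom
  meta <- list(
    geometry = list(S = g$S, alpha_deg = g$alpha, placement = g$placement,
                    X0_um = g$X0, Y0_um = g$Y0, Z0_um = g$Z0,
                    fillet_um = g$fillet_radius, throat_um = g$throat),
    fluid = list(name = flow$fluid$name, rho = flow$fluid$rho,
                 law = flow$fluid$law),
    operating = list(gamma0_s_inv = flow$gamma0,
                     Q_uL_min = flow$op$Q_uL_min, Re = flow$op$Re),
    grid = list(nx = flow$grid$nx, ny = flow$grid$ny),
    solve = list(iterations = flow$iterations,
                 final_residual = utils::tail(flow$residual_history$res_psi, 1),
                 mass_imbalance = flow$mass_imbalance,
                 converged = flow$converged)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a platelet-trajectory profile as CSV
#'
#' Columns: `x_um`, `gamma_s_inv`, `gamma_prime_um_inv_s_inv`.
#'
#' @param profile a [platelet_trajectory_profile()] result.
#' @param path output `.csv` path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "shear_profile"))
  utils::write.csv(data.frame(x_um = profile$x_um,
                              gamma_s_inv = profile$gamma_s,
                              gamma_prime_um_inv_s_inv = profile$gamma_prime),
                   path, row.names = FALSE)
  invisible(path)
}
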